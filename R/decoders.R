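# Decoding strategies ---------------------------------------------------------------
#
# Three decoders over the pull-based model contract (decode_init/decode_step):
#
#  * greedy  - argmax token by token;
#  * beam    - breadth-limited search under a length-normalised
#              log-probability score;
#  * mcts    - reward-guided Monte Carlo Tree Search: UCT selection,
#              full-vocabulary expansion, prior-guided rollouts scored by the
#              reward function, and reward back-propagation.
#
# Token lists returned by the decoders contain chemical tokens only (no
# BOS/EOS); join them with detokenize_smiles() to obtain the SMILES string.

#' Greedy decoding
#'
#' At each step emits the token with the highest model probability, breaking
#' ties toward the lowest vocabulary index; stops at EOS or after `max_len`
#' tokens.  Deterministic for a fixed model and context.
#'
#' @param model,ctx Model and protein context.
#' @param max_len Maximum number of chemical tokens.
#' @return Character vector of emitted tokens (EOS excluded).
#' @export
greedy_decode <- function(model, ctx, max_len = 64L) {
  stopifnot(max_len >= 1)
  vocab <- model_vocab(model)
  tokens <- character(0)
  r <- decode_step(model, decode_init(model, ctx), vocab$bos)
  repeat {
    tok <- vocab$tokens[[which.max(r$probs)]]
    if (tok == vocab$eos) {
      break
    }
    tokens <- c(tokens, tok)
    if (length(tokens) >= max_len) {
      break
    }
    r <- decode_step(model, r$state, tok)
  }
  tokens
}

#' Beam-search decoding
#'
#' Keeps the `k` highest-scoring partial sequences per step under the score
#' `sum(log p) / len^length_alpha` (with `length_alpha = 0` the raw
#' log-probability).  A sequence finishes when it emits EOS or reaches
#' `max_len`; finished sequences occupy beam slots and compete in the final
#' ranking.  With `k = 1` this reduces to [greedy_decode()] token for token.
#'
#' @param model,ctx Model and protein context.
#' @param k Beam width (>= 1).
#' @param length_alpha Length-normalisation exponent (>= 0).
#' @param max_len Maximum number of chemical tokens per sequence.
#' @return A list of at most `k` finished candidates sorted by score
#'   (descending); each is `list(tokens, score, logp)`.
#' @export
beam_decode <- function(model, ctx, k = 2L, length_alpha = 0,
                        max_len = 64L) {
  stopifnot(k >= 1, max_len >= 1, length_alpha >= 0)
  vocab <- model_vocab(model)
  eos_id <- unname(vocab$index[vocab$eos])
  score_of <- function(logp, len) logp / max(len, 1L)^length_alpha
  r0 <- decode_step(model, decode_init(model, ctx), vocab$bos)
  active <- list(list(tokens = character(0), logp = 0, r = r0))
  finished <- list()
  for (step in seq_len(max_len)) {
    cand <- list()
    for (b in active) {
      probs <- b$r$probs
      for (i in which(probs > 0)) {
        tok <- vocab$tokens[[i]]
        is_eos <- i == eos_id
        len <- length(b$tokens) + 1L
        logp <- b$logp + log(probs[[i]])
        cand[[length(cand) + 1L]] <-
          list(tokens = if (is_eos) b$tokens else c(b$tokens, tok),
               logp = logp, finished = is_eos, parent = b,
               score = score_of(logp, len))
      }
    }
    if (length(cand) == 0L) {
      break
    }
    ord <- order(vapply(cand, `[[`, numeric(1), "score"),
                 decreasing = TRUE)
    top <- cand[ord[seq_len(min(k, length(cand)))]]
    active <- list()
    for (cd in top) {
      if (cd$finished || length(cd$tokens) >= max_len) {
        finished[[length(finished) + 1L]] <-
          list(tokens = cd$tokens, score = cd$score, logp = cd$logp)
      } else {
        tok <- cd$tokens[[length(cd$tokens)]]
        active[[length(active) + 1L]] <-
          list(tokens = cd$tokens, logp = cd$logp,
               r = decode_step(model, cd$parent$r$state, tok))
      }
    }
    if (length(active) == 0L) {
      break
    }
  }
  # anything still active at the depth limit competes as-is
  for (b in active) {
    finished[[length(finished) + 1L]] <-
      list(tokens = b$tokens, score = score_of(b$logp, length(b$tokens)),
           logp = b$logp)
  }
  finished <- finished[order(vapply(finished, `[[`, numeric(1), "score"),
                             decreasing = TRUE)]
  utils::head(finished, k)
}

# MCTS -------------------------------------------------------------------------------

#' MCTS search parameters
#'
#' @param c_explore Exploration constant of the UCT rule (default 2).
#' @param n_simulations Simulation budget per generated molecule.
#' @param max_depth Maximum chemical-token depth of a sequence.
#' @param rollouts_per_expansion Rollouts scored (and back-propagated) per
#'   simulation; default 1.
#' @param seed Integer seed governing every stochastic draw of the search.
#' @return An `mcts_config`.
#' @export
mcts_config <- function(c_explore = 2, n_simulations = 100L, max_depth = 32L,
                        rollouts_per_expansion = 1L, seed = 1L) {
  stopifnot(c_explore >= 0, n_simulations >= 1, max_depth >= 1,
            rollouts_per_expansion >= 1)
  structure(list(c_explore = c_explore,
                 n_simulations = as.integer(n_simulations),
                 max_depth = as.integer(max_depth),
                 rollouts_per_expansion = as.integer(rollouts_per_expansion),
                 seed = as.integer(seed)),
            class = "mcts_config")
}

# Tree nodes are mutable environments: token, parent, children (list),
# n_visits, cum_reward, terminal flag and depth (chemical tokens so far).
new_tree_node <- function(token, parent = NULL, terminal = FALSE,
                          depth = 0L) {
  node <- new.env(parent = emptyenv())
  node$token <- token
  node$parent <- parent
  node$children <- list()
  node$n_visits <- 0L
  node$cum_reward <- 0
  node$terminal <- terminal
  node$depth <- depth
  class(node) <- "tree_node"
  node
}

#' Upper Confidence Bound for tree search (UCT)
#'
#' `cum_reward / n_visits + c * sqrt(log(parent_visits) / n_visits)`.
#' Unvisited nodes score `+Inf`, so every child is tried once before any is
#' revisited.
#'
#' @param node A `tree_node` (or any list/environment with `cum_reward` and
#'   `n_visits`).
#' @param parent_visits Visit count of the parent (>= 1).
#' @param c_explore Exploration constant.
#' @return The UCT score.
#' @export
ucb_score <- function(node, parent_visits, c_explore = 2) {
  stopifnot(parent_visits >= 1)
  n <- node$n_visits
  if (n == 0L) {
    return(Inf)
  }
  node$cum_reward / n + c_explore * sqrt(log(parent_visits) / n)
}

#' Generate one molecule by reward-guided MCTS
#'
#' Runs `n_simulations` iterations of the four-phase search over the SMILES
#' token tree rooted at BOS:
#'
#' 1. *Selection*: descend from the root, at each level taking the child with
#'    the highest [ucb_score()] (ties to the lowest token index), until a
#'    leaf is reached.
#' 2. *Expansion*: if the leaf is non-terminal, create one child per
#'    vocabulary token with positive model probability at that prefix.
#' 3. *Simulation*: from the first unvisited child, complete the sequence by
#'    sampling tokens from the model's next-token distribution (the
#'    informative prior) until EOS or `max_depth`, then score the SMILES with
#'    [compute_reward()].
#' 4. *Backpropagation*: add the composite reward to `cum_reward` and
#'    increment `n_visits` on every node from the expanded child up to the
#'    root.
#'
#' The returned molecule is the highest-composite-reward *valid* terminal
#' sequence observed across all simulations; if no valid terminal was ever
#' reached the function throws an error rather than return an invalid SMILES.
#'
#' @param model,ctx Model and protein context.
#' @param reward_cfg A [reward_config()].
#' @param search_cfg An [mcts_config()].
#' @param scorer Optional affinity scorer passed to [compute_reward()].
#' @return A `generation_result`: list with `smiles`, `reward`
#'   (`reward_vector`), `decoder = "mcts"`, `simulations_used`, `seed` and
#'   the search tree `root` (for diagnostics).
#' @export
mcts_generate <- function(model, ctx, reward_cfg = reward_config(),
                          search_cfg = mcts_config(), scorer = NULL) {
  stopifnot(inherits(search_cfg, "mcts_config"))
  vocab <- model_vocab(model)
  eos <- vocab$eos
  root <- new_tree_node(vocab$bos)
  best <- NULL

  with_seed(search_cfg$seed, {
    for (sim in seq_len(search_cfg$n_simulations)) {
      # 1. selection: replay the path's decode state as we descend
      node <- root
      r <- decode_step(model, decode_init(model, ctx), vocab$bos)
      path_tokens <- character(0)
      while (length(node$children) > 0L) {
        pv <- max(node$n_visits, 1L)
        scores <- vapply(node$children, ucb_score, numeric(1),
                         parent_visits = pv,
                         c_explore = search_cfg$c_explore)
        node <- node$children[[which.max(scores)]]
        if (node$token != eos) {
          path_tokens <- c(path_tokens, node$token)
          if (!node$terminal) {
            r <- decode_step(model, r$state, node$token)
          }
        }
      }

      # 2. expansion
      sim_node <- node
      sim_tokens <- path_tokens
      sim_r <- r
      if (!node$terminal) {
        probs <- r$probs
        for (i in which(probs > 0)) {
          tok <- vocab$tokens[[i]]
          depth <- node$depth + (tok != eos)
          node$children[[length(node$children) + 1L]] <-
            new_tree_node(tok, parent = node,
                          terminal = tok == eos ||
                            depth >= search_cfg$max_depth,
                          depth = depth)
        }
        if (length(node$children) > 0L) {
          sim_node <- node$children[[1L]]  # first (necessarily unvisited)
          if (sim_node$token != eos) {
            sim_tokens <- c(sim_tokens, sim_node$token)
            if (!sim_node$terminal) {
              sim_r <- decode_step(model, r$state, sim_node$token)
            }
          }
        }
      }

      # 3. simulation (rollout) + 4. backpropagation
      for (rollout in seq_len(search_cfg$rollouts_per_expansion)) {
        tokens <- sim_tokens
        if (!sim_node$terminal) {
          rr <- sim_r
          while (length(tokens) < search_cfg$max_depth) {
            i <- sample.int(length(rr$probs), 1L, prob = rr$probs)
            tok <- vocab$tokens[[i]]
            if (tok == eos) {
              break
            }
            tokens <- c(tokens, tok)
            if (length(tokens) >= search_cfg$max_depth) {
              break
            }
            rr <- decode_step(model, rr$state, tok)
          }
        }
        smiles <- detokenize_smiles(tokens)
        reward <- compute_reward(smiles, reward_cfg, scorer)
        if (reward$validity == 1 &&
            (is.null(best) || reward$composite > best$composite)) {
          best <- reward
        }
        n <- sim_node
        while (!is.null(n)) {
          n$n_visits <- n$n_visits + 1L
          n$cum_reward <- n$cum_reward + reward$composite
          n <- n$parent
        }
      }
    }
  })

  if (is.null(best)) {
    stop("MCTS exhausted its budget (", search_cfg$n_simulations,
         " simulations) without reaching a valid terminal sequence")
  }
  structure(list(smiles = best$smiles, reward = best, decoder = "mcts",
                 simulations_used = search_cfg$n_simulations,
                 seed = search_cfg$seed, root = root),
            class = "generation_result")
}

#' @export
print.generation_result <- function(x, ...) {
  cat("<generation_result> [", x$decoder, "] ", x$smiles,
      "  (composite reward ", round(x$reward$composite, 4), ", ",
      x$simulations_used, " simulations, seed ", x$seed, ")\n", sep = "")
  invisible(x)
}
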