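# Shared fixtures: mock-model builders and small independent oracles.

mpro_fixture <- function() {
  read_smi(system.file("extdata", "mpro_reference_ligands.smi",
                       package = "mctsmol"))$smiles
}

template_fixture <- function() {
  read_smi(system.file("extdata", "ligand_templates.smi",
                       package = "mctsmol"))$smiles
}

# A complete random transition table over `tokens` + EOS for every prefix
# shorter than max_len, so any decode is well-defined.
random_mock_model <- function(n_tokens = 3L, max_len = 4L, seed = 1L) {
  tokens <- head(c("C", "O", "N", "F"), n_tokens)
  support <- c(tokens, "<eos>")
  set.seed(seed)
  table <- list()
  prefixes <- list(character(0))
  for (len in 0:(max_len - 1L)) {
    next_prefixes <- list()
    for (pf in prefixes) {
      key <- paste(c("<bos>", pf), collapse = " ")
      p <- stats::runif(length(support), 0.01, 1)
      table[[key]] <- stats::setNames(p / sum(p), support)
      if (len < max_len - 1L) {
        for (tok in tokens) {
          next_prefixes[[length(next_prefixes) + 1L]] <- c(pf, tok)
        }
      }
    }
    prefixes <- next_prefixes
  }
  mock_model(table, tokens = tokens)
}

# Exhaustive-enumeration oracle for beam search: walks every token sequence
# of chemical length <= max_len and scores finished sequences exactly as the
# beam scorer defines (steps include the EOS emission; truncated sequences
# count max_len steps).
enumerate_best <- function(model, ctx, length_alpha, max_len) {
  vocab <- model$vocab
  best <- list(score = -Inf, tokens = NULL)
  recurse <- function(prefix, logp, r) {
    probs <- r$probs
    for (i in which(probs > 0)) {
      tok <- vocab$tokens[[i]]
      lp <- logp + log(probs[[i]])
      if (tok == vocab$eos) {
        steps <- length(prefix) + 1L
        score <- lp / steps^length_alpha
        if (score > best$score) {
          best <<- list(score = score, tokens = prefix)
        }
      } else {
        seq <- c(prefix, tok)
        if (length(seq) >= max_len) {
          score <- lp / max_len^length_alpha
          if (score > best$score) {
            best <<- list(score = score, tokens = seq)
          }
        } else {
          recurse(seq, lp, decode_step(model, r$state, tok))
        }
      }
    }
  }
  recurse(character(0), 0,
          decode_step(model, decode_init(model, ctx), vocab$bos))
  best
}

# Independent re-statement of the record-filtering rule, written as literal
# branching rather than vectorised logic.
brute_force_filter <- function(records) {
  keep <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (is.na(r$organism) || r$organism != "Homo sapiens") next
    if (is.na(r$smiles) || nchar(r$smiles) == 0) next
    if (!is.na(r$ic50_nM)) {
      keep[i] <- r$ic50_nM < 100
    } else if (!is.na(r$kd_nM)) {
      keep[i] <- r$kd_nM < 100
    } else if (!is.na(r$ec50_nM)) {
      keep[i] <- r$ec50_nM < 100
    }
  }
  which(keep)
}

# Random records exercising every missing-data pattern for the filter oracle.
random_records <- function(n, seed) {
  set.seed(seed)
  maybe <- function(vals) sample(vals, n, replace = TRUE)
  num_or_na <- function() ifelse(stats::runif(n) < 0.4, NA_real_,
                                 stats::runif(n, 0, 200))
  data.frame(organism = maybe(c("Homo sapiens", "Homo sapiens",
                                "Mus musculus", NA)),
             ic50_nM = num_or_na(), kd_nM = num_or_na(),
             ec50_nM = num_or_na(),
             smiles = maybe(c("CCO", "c1ccccc1", NA, "")),
             protein_seq = "MKVLA", stringsAsFactors = FALSE)
}

# Verify MCTS tree bookkeeping: visits conserve down the tree and cumulative
# rewards are bounded by visits times the maximum composite reward.
check_tree_invariants <- function(node, max_reward) {
  kid_visits <- 0L
  for (child in node$children) {
    kid_visits <- kid_visits + child$n_visits
    check_tree_invariants(child, max_reward)
  }
  expect_gte(node$n_visits, kid_visits)
  expect_lte(node$cum_reward, node$n_visits * max_reward + 1e-9)
}
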