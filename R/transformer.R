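# Conditional SMILES language model ---------------------------------------------
#
# An encoder-decoder transformer: the encoder self-attends over a protein
# amino-acid sequence to build a per-residue context; the decoder generates
# SMILES tokens autoregressively, attending to that context (cross-attention)
# and to its own prefix (causal self-attention).  Training uses teacher
# forcing with a cross-entropy loss and the Adam optimizer; gradients are
# written out by hand and verified against finite differences in the test
# suite.  Blocks use residual connections without layer normalization, which
# at the shallow depths used here trains stably and keeps the backward pass
# transparent.

`%||%` <- function(a, b) if (is.null(a)) b else a

.AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

#' Transformer hyper-parameters
#'
#' Defaults are the full-scale training regime (six 512-wide blocks with
#' eight attention heads, Adam at 1e-4, batches of five, 25 epochs).  For
#' desk-scale work use [toy_transformer_config()].
#'
#' @param n_layers Encoder and decoder block count.
#' @param d_model Model width; must be even and divisible by `n_heads`.
#' @param n_heads Attention heads per block.
#' @param d_ff Width of the position-wise feed-forward layer.
#' @param learning_rate Adam step size.
#' @param batch_size Pairs per gradient step (gradient accumulation).
#' @param n_epochs Training epochs.
#' @param max_protein_len,max_smiles_len Hard sequence-length limits.
#' @param seed Seed for weight initialization and epoch shuffling.
#' @return A `transformer_config` list.
#' @export
transformer_config <- function(n_layers = 6, d_model = 512, n_heads = 8,
                               d_ff = 2L * d_model, learning_rate = 1e-4,
                               batch_size = 5, n_epochs = 25,
                               max_protein_len = 500, max_smiles_len = 64,
                               seed = 1L) {
  stopifnot(n_layers >= 1, d_model >= 2, n_heads >= 1,
            d_model %% n_heads == 0, d_model %% 2 == 0, d_ff >= 1,
            learning_rate > 0, batch_size >= 1, n_epochs >= 1,
            max_protein_len >= 1, max_smiles_len >= 1)
  structure(list(n_layers = as.integer(n_layers),
                 d_model = as.integer(d_model),
                 n_heads = as.integer(n_heads), d_ff = as.integer(d_ff),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 n_epochs = as.integer(n_epochs),
                 max_protein_len = as.integer(max_protein_len),
                 max_smiles_len = as.integer(max_smiles_len),
                 seed = as.integer(seed)),
            class = "transformer_config")
}

#' Reduced configuration for desk-scale training
#'
#' Two 32-wide blocks with four heads; enough capacity to memorise a small
#' synthetic ligand corpus in a couple of minutes on one CPU.
#'
#' @param ... Overrides passed to [transformer_config()].
#' @export
toy_transformer_config <- function(...) {
  defaults <- list(n_layers = 2, d_model = 32, n_heads = 4, d_ff = 64,
                   learning_rate = 3e-3, batch_size = 5, n_epochs = 15,
                   max_protein_len = 300, max_smiles_len = 32, seed = 1L)
  args <- utils::modifyList(defaults, list(...))
  do.call(transformer_config, args)
}

# -- numerics -------------------------------------------------------------------

softmax_rows <- function(S) {
  m <- apply(S, 1L, max)
  E <- exp(S - m)
  E / rowSums(E)
}

# Sinusoidal positional encodings, L x d (positions are 0-based).
positional_encoding <- function(L, d) {
  pos <- seq_len(L) - 1
  k <- seq_len(d %/% 2) - 1
  freq <- 1 / (10000^(2 * k / d))
  arg <- outer(pos, freq)
  pe <- matrix(0, L, d)
  pe[, 2 * k + 1] <- sin(arg)
  pe[, 2 * k + 2] <- cos(arg)
  pe
}

xavier_init <- function(nrow, ncol) {
  s <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -s, s), nrow, ncol)
}

# -- multi-head attention -------------------------------------------------------

# Xq: Lq x d queries source; Xkv: Lk x d keys/values source.
# p: list(Wq, Wk, Wv, Wo), each d x d.
mha_forward <- function(Xq, Xkv, p, n_heads, causal = FALSE) {
  d <- ncol(Xq)
  dh <- d %/% n_heads
  Q <- Xq %*% p$Wq
  K <- Xkv %*% p$Wk
  V <- Xkv %*% p$Wv
  H <- matrix(0, nrow(Xq), d)
  A_heads <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1L) * dh + 1L):(h * dh)
    S <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) / sqrt(dh)
    if (causal) {
      S[upper.tri(S)] <- -Inf
    }
    A <- softmax_rows(S)
    A_heads[[h]] <- A
    H[, idx] <- A %*% V[, idx, drop = FALSE]
  }
  list(out = H %*% p$Wo,
       cache = list(Xq = Xq, Xkv = Xkv, Q = Q, K = K, V = V, H = H,
                    A = A_heads, n_heads = n_heads, p = p))
}

mha_backward <- function(dOut, cache) {
  p <- cache$p
  d <- ncol(cache$Q)
  n_heads <- cache$n_heads
  dh <- d %/% n_heads
  dH <- dOut %*% t(p$Wo)
  dWo <- crossprod(cache$H, dOut)
  dQ <- matrix(0, nrow(cache$Q), d)
  dK <- matrix(0, nrow(cache$K), d)
  dV <- matrix(0, nrow(cache$V), d)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1L) * dh + 1L):(h * dh)
    A <- cache$A[[h]]
    dHh <- dH[, idx, drop = FALSE]
    dA <- tcrossprod(dHh, cache$V[, idx, drop = FALSE])
    dV[, idx] <- crossprod(A, dHh)
    # softmax jacobian, row-wise; masked cells have A == 0 hence dS == 0
    dS <- A * (dA - rowSums(dA * A))
    dQ[, idx] <- dS %*% cache$K[, idx, drop = FALSE] / sqrt(dh)
    dK[, idx] <- crossprod(dS, cache$Q[, idx, drop = FALSE]) / sqrt(dh)
  }
  list(dXq = dQ %*% t(p$Wq),
       dXkv = dK %*% t(p$Wk) + dV %*% t(p$Wv),
       grads = list(Wq = crossprod(cache$Xq, dQ),
                    Wk = crossprod(cache$Xkv, dK),
                    Wv = crossprod(cache$Xkv, dV),
                    Wo = dWo))
}

# -- position-wise feed-forward -------------------------------------------------

ffn_forward <- function(X, p) {
  Z <- sweep(X %*% p$W1, 2L, p$b1, "+")
  Hr <- pmax(Z, 0)
  list(out = sweep(Hr %*% p$W2, 2L, p$b2, "+"),
       cache = list(X = X, Z = Z, Hr = Hr, p = p))
}

ffn_backward <- function(dOut, cache) {
  p <- cache$p
  dHr <- dOut %*% t(p$W2)
  dZ <- dHr * (cache$Z > 0)
  list(dX = dZ %*% t(p$W1),
       grads = list(W1 = crossprod(cache$X, dZ), b1 = colSums(dZ),
                    W2 = crossprod(cache$Hr, dOut), b2 = colSums(dOut)))
}

# -- parameter tree utilities ---------------------------------------------------

init_attn_params <- function(d) {
  list(Wq = xavier_init(d, d), Wk = xavier_init(d, d),
       Wv = xavier_init(d, d), Wo = xavier_init(d, d))
}

init_ffn_params <- function(d, d_ff) {
  list(W1 = xavier_init(d, d_ff), b1 = numeric(d_ff),
       W2 = xavier_init(d_ff, d), b2 = numeric(d))
}

init_params <- function(config, n_aa, n_vocab) {
  d <- config$d_model
  enc <- lapply(seq_len(config$n_layers), function(i) {
    list(attn = init_attn_params(d), ffn = init_ffn_params(d, config$d_ff))
  })
  dec <- lapply(seq_len(config$n_layers), function(i) {
    list(self = init_attn_params(d), cross = init_attn_params(d),
         ffn = init_ffn_params(d, config$d_ff))
  })
  list(emb_protein = xavier_init(n_aa, d),
       emb_smiles = xavier_init(n_vocab, d),
       W_out = xavier_init(d, n_vocab), b_out = numeric(n_vocab),
       enc = enc, dec = dec)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- mapply(tree_map2, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
    names(out) <- names(a)
    out
  } else {
    f(a, b)
  }
}

tree_map <- function(f, a) {
  if (is.list(a)) {
    out <- lapply(a, tree_map, f = f)
    names(out) <- names(a)
    out
  } else {
    f(a)
  }
}

tree_add <- function(a, b) tree_map2(`+`, a, b)
tree_zero <- function(a) tree_map(function(x) x * 0, a)

# One Adam step over a parameter tree; state holds first/second moments and
# the step counter.
adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.null(state)) {
    state <- list(m = tree_zero(params), v = tree_zero(params), t = 0L)
  }
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  mhat <- tree_map(function(m) m / corr1, state$m)
  vhat <- tree_map(function(v) v / corr2, state$v)
  params <- tree_map2(function(p, u) p - lr * u, params,
                      tree_map2(function(m, v) m / (sqrt(v) + eps),
                                mhat, vhat))
  list(params = params, state = state)
}

# -- encoder / decoder forward & backward ---------------------------------------

encoder_forward <- function(params, config, aa_ids) {
  X <- params$emb_protein[aa_ids, , drop = FALSE] +
    positional_encoding(length(aa_ids), config$d_model)
  caches <- vector("list", config$n_layers)
  for (l in seq_len(config$n_layers)) {
    a <- mha_forward(X, X, params$enc[[l]]$attn, config$n_heads)
    X1 <- X + a$out
    f <- ffn_forward(X1, params$enc[[l]]$ffn)
    caches[[l]] <- list(attn = a$cache, ffn = f$cache)
    X <- X1 + f$out
  }
  list(out = X, caches = caches)
}

encoder_backward <- function(dOut, fwd, params, config, aa_ids) {
  grads <- list(enc = vector("list", config$n_layers))
  dX <- dOut
  for (l in rev(seq_len(config$n_layers))) {
    fb <- ffn_backward(dX, fwd$caches[[l]]$ffn)
    dX1 <- dX + fb$dX
    ab <- mha_backward(dX1, fwd$caches[[l]]$attn)
    dX <- dX1 + ab$dXq + ab$dXkv
    grads$enc[[l]] <- list(attn = ab$grads, ffn = fb$grads)
  }
  demb <- matrix(0, nrow(params$emb_protein), config$d_model)
  acc <- rowsum(dX, group = aa_ids)
  demb[as.integer(rownames(acc)), ] <- acc
  grads$emb_protein <- demb
  grads
}

decoder_forward <- function(params, config, enc_out, in_ids) {
  Y <- params$emb_smiles[in_ids, , drop = FALSE] +
    positional_encoding(length(in_ids), config$d_model)
  caches <- vector("list", config$n_layers)
  for (l in seq_len(config$n_layers)) {
    s <- mha_forward(Y, Y, params$dec[[l]]$self, config$n_heads, causal = TRUE)
    Y1 <- Y + s$out
    x <- mha_forward(Y1, enc_out, params$dec[[l]]$cross, config$n_heads)
    Y2 <- Y1 + x$out
    f <- ffn_forward(Y2, params$dec[[l]]$ffn)
    caches[[l]] <- list(self = s$cache, cross = x$cache, ffn = f$cache)
    Y <- Y2 + f$out
  }
  logits <- sweep(Y %*% params$W_out, 2L, params$b_out, "+")
  list(logits = logits, Y = Y, caches = caches)
}

decoder_backward <- function(dLogits, fwd, params, config, enc_out, in_ids) {
  grads <- list(dec = vector("list", config$n_layers))
  grads$W_out <- crossprod(fwd$Y, dLogits)
  grads$b_out <- colSums(dLogits)
  dY <- dLogits %*% t(params$W_out)
  dEnc <- matrix(0, nrow(enc_out), config$d_model)
  for (l in rev(seq_len(config$n_layers))) {
    fb <- ffn_backward(dY, fwd$caches[[l]]$ffn)
    dY2 <- dY + fb$dX
    xb <- mha_backward(dY2, fwd$caches[[l]]$cross)
    dEnc <- dEnc + xb$dXkv
    dY1 <- dY2 + xb$dXq
    sb <- mha_backward(dY1, fwd$caches[[l]]$self)
    dY <- dY1 + sb$dXq + sb$dXkv
    grads$dec[[l]] <- list(self = sb$grads, cross = xb$grads, ffn = fb$grads)
  }
  demb <- matrix(0, nrow(params$emb_smiles), config$d_model)
  acc <- rowsum(dY, group = in_ids)
  demb[as.integer(rownames(acc)), ] <- acc
  grads$emb_smiles <- demb
  grads$dEnc <- dEnc
  grads
}

# Cross-entropy over one teacher-forced sequence.  Returns the mean loss and
# the gradient w.r.t. the logits.
cross_entropy <- function(logits, target_ids) {
  P <- softmax_rows(logits)
  n <- length(target_ids)
  picked <- P[cbind(seq_len(n), target_ids)]
  loss <- -mean(log(pmax(picked, 1e-300)))
  dLogits <- P
  dLogits[cbind(seq_len(n), target_ids)] <-
    dLogits[cbind(seq_len(n), target_ids)] - 1
  list(loss = loss, dLogits = dLogits / n)
}

# Loss and gradients for one (protein, SMILES-token-ids) pair.
pair_loss_and_grads <- function(params, config, aa_ids, smiles_ids,
                                want_grads = TRUE) {
  in_ids <- smiles_ids$input
  target_ids <- smiles_ids$target
  enc <- encoder_forward(params, config, aa_ids)
  dec <- decoder_forward(params, config, enc$out, in_ids)
  ce <- cross_entropy(dec$logits, target_ids)
  if (!want_grads) {
    return(list(loss = ce$loss))
  }
  dg <- decoder_backward(ce$dLogits, dec, params, config, enc$out, in_ids)
  eg <- encoder_backward(dg$dEnc, enc, params, config, aa_ids)
  dg$dEnc <- NULL
  grads <- c(dg[c("emb_smiles", "W_out", "b_out", "dec")],
             eg[c("emb_protein", "enc")])
  # put in the same order as the parameter tree
  grads <- grads[c("emb_protein", "emb_smiles", "W_out", "b_out",
                   "enc", "dec")]
  list(loss = ce$loss, grads = grads)
}

# -- public model API -----------------------------------------------------------

aa_to_ids <- function(protein_seq, max_len) {
  stopifnot(is.character(protein_seq), length(protein_seq) == 1L)
  if (nchar(protein_seq) == 0L) {
    stop("protein sequence is empty")
  }
  if (nchar(protein_seq) > max_len) {
    stop("protein sequence has ", nchar(protein_seq),
         " residues, exceeding max_protein_len = ", max_len)
  }
  chars <- strsplit(protein_seq, "", fixed = TRUE)[[1L]]
  ids <- match(chars, .AA_LETTERS)
  if (anyNA(ids)) {
    bad <- unique(chars[is.na(ids)])
    stop("illegal residue character(s): ", paste(bad, collapse = ", "),
         " (allowed: the 20 standard residues plus X)")
  }
  ids
}

smiles_to_ids <- function(smiles, vocab, max_len) {
  toks <- tokenize_smiles(smiles, vocab)
  if (length(toks) + 1L > max_len) {
    stop("SMILES has ", length(toks), " tokens, exceeding max_smiles_len = ",
         max_len)
  }
  ids <- unname(vocab$index[toks])
  list(input = c(unname(vocab$index[vocab$bos]), ids),
       target = c(ids, unname(vocab$index[vocab$eos])))
}

# Run expr with a private, seeded RNG stream, restoring the caller's state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Train the conditional SMILES transformer
#'
#' Teacher-forced maximum-likelihood training of the encoder-decoder model on
#' (protein sequence, SMILES) pairs.  All SMILES must be valid; the token
#' vocabulary is built from the training corpus and frozen into the model.
#'
#' @param pairs A data.frame with character columns `protein_seq` and
#'   `smiles` (at least two rows).
#' @param config A [transformer_config()]; use [toy_transformer_config()] for
#'   desk-scale runs.
#' @return A `smiles_transformer` with the learned parameters, the frozen
#'   vocabulary and a `loss_history` (`initial` plus one mean cross-entropy
#'   per epoch).
#' @export
train_toy <- function(pairs, config = toy_transformer_config()) {
  pairs <- as.data.frame(pairs)
  stopifnot(all(c("protein_seq", "smiles") %in% names(pairs)))
  if (nrow(pairs) < 2L) {
    stop("need at least 2 training pairs")
  }
  ok <- is_valid_smiles(pairs$smiles)
  if (!all(ok)) {
    stop("invalid SMILES in training pairs: ",
         paste(dQuote(utils::head(pairs$smiles[!ok], 5L)), collapse = ", "))
  }
  vocab <- smiles_vocabulary(pairs$smiles)
  aa_ids <- lapply(pairs$protein_seq, aa_to_ids, config$max_protein_len)
  tok_ids <- lapply(pairs$smiles, smiles_to_ids, vocab, config$max_smiles_len)
  n <- nrow(pairs)

  with_seed(config$seed, {
    params <- init_params(config, n_aa = length(.AA_LETTERS),
                          n_vocab = length(vocab$tokens))
    initial_loss <- mean(vapply(seq_len(n), function(i) {
      pair_loss_and_grads(params, config, aa_ids[[i]], tok_ids[[i]],
                          want_grads = FALSE)$loss
    }, numeric(1)))
    state <- NULL
    epoch_loss <- numeric(config$n_epochs)
    for (epoch in seq_len(config$n_epochs)) {
      order <- sample.int(n)
      acc <- NULL
      acc_n <- 0L
      losses <- numeric(n)
      for (j in seq_along(order)) {
        i <- order[[j]]
        res <- pair_loss_and_grads(params, config, aa_ids[[i]], tok_ids[[i]])
        losses[[j]] <- res$loss
        acc <- if (is.null(acc)) res$grads else tree_add(acc, res$grads)
        acc_n <- acc_n + 1L
        if (acc_n == config$batch_size || j == n) {
          mean_grads <- tree_map(function(g) g / acc_n, acc)
          upd <- adam_step(params, mean_grads, state, config$learning_rate)
          params <- upd$params
          state <- upd$state
          acc <- NULL
          acc_n <- 0L
        }
      }
      epoch_loss[[epoch]] <- mean(losses)
    }
    structure(list(params = params, config = config, vocab = vocab,
                   uid = paste0("m", paste(sample(c(letters, 0:9), 12,
                                                  replace = TRUE),
                                           collapse = "")),
                   loss_history = c(initial = initial_loss,
                                    stats::setNames(epoch_loss,
                                                    paste0("epoch_",
                                                           seq_len(config$n_epochs))))),
              class = "smiles_transformer")
  })
}

#' @export
print.smiles_transformer <- function(x, ...) {
  cat("<smiles_transformer> ", x$config$n_layers, " layers, d_model ",
      x$config$d_model, ", ", x$config$n_heads, " heads, vocabulary ",
      length(x$vocab$tokens), " tokens\n", sep = "")
  cat("  training loss: ", round(x$loss_history[[1L]], 4), " -> ",
      round(x$loss_history[[length(x$loss_history)]], 4), "\n", sep = "")
  invisible(x)
}

#' Save / load a trained model
#'
#' Checkpoints embed the configuration and the frozen vocabulary.
#' @param model A `smiles_transformer`.
#' @param path File path.
#' @return `save_model` invisibly returns `path`; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "smiles_transformer"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "smiles_transformer"))
  model
}

#' Encode a protein sequence into a context
#'
#' Runs the encoder over the amino-acid sequence and pre-computes the
#' cross-attention keys and values used by every decoder layer.  The context
#' is tied to the model instance that produced it.
#'
#' @param model A trained model (or mock).
#' @param protein_seq Amino-acid string over the 20 standard residues plus X.
#' @return A `protein_context`.
#' @export
encode <- function(model, protein_seq) {
  UseMethod("encode")
}

#' @export
encode.smiles_transformer <- function(model, protein_seq) {
  aa_ids <- aa_to_ids(protein_seq, model$config$max_protein_len)
  enc <- encoder_forward(model$params, model$config, aa_ids)
  cross <- lapply(model$params$dec, function(layer) {
    list(K = enc$out %*% layer$cross$Wk, V = enc$out %*% layer$cross$Wv)
  })
  structure(list(enc_out = enc$out, cross = cross, uid = model$uid,
                 length = length(aa_ids)),
            class = "protein_context")
}

#' @export
print.protein_context <- function(x, ...) {
  cat("<protein_context> ", x$length, " residues\n", sep = "")
  invisible(x)
}

# -- incremental decoding API ---------------------------------------------------

#' Begin an incremental decode
#'
#' Returns an empty decoder state; feed tokens (starting with BOS) through
#' [decode_step()] to obtain next-token distributions.  All decoders (greedy,
#' beam, MCTS) are written against this pull-based contract, so the
#' transformer and the table-driven [mock_model()] are interchangeable.
#'
#' @param model A `smiles_transformer` or `mock_model`.
#' @param ctx A `protein_context` from [encode()].
#' @return An opaque decoder state.
#' @export
decode_init <- function(model, ctx) {
  UseMethod("decode_init")
}

#' Consume one token and return the next-token distribution
#'
#' @param model,state Model and the state returned by [decode_init()] or a
#'   previous step.
#' @param token The token just appended to the sequence (BOS first).
#' @return `list(probs, state)`: `probs` is a probability vector named by the
#'   vocabulary tokens (zero mass on PAD and BOS), `state` the advanced state.
#' @export
decode_step <- function(model, state, token) {
  UseMethod("decode_step")
}

#' @export
decode_init.smiles_transformer <- function(model, ctx) {
  if (!inherits(ctx, "protein_context") || !identical(ctx$uid, model$uid)) {
    stop("context was not produced by this model instance")
  }
  nl <- model$config$n_layers
  list(t = 0L, K = vector("list", nl), V = vector("list", nl), ctx = ctx)
}

#' @export
decode_step.smiles_transformer <- function(model, state, token) {
  vocab <- model$vocab
  id <- vocab$index[token]
  if (is.na(id)) {
    stop("token outside vocabulary: ", dQuote(token))
  }
  p <- model$params
  cfg <- model$config
  d <- cfg$d_model
  dh <- d %/% cfg$n_heads
  t <- state$t + 1L
  if (t > cfg$max_smiles_len) {
    stop("decode exceeded max_smiles_len = ", cfg$max_smiles_len)
  }
  pe <- positional_encoding(t, d)[t, , drop = FALSE]
  y <- p$emb_smiles[id, , drop = FALSE] + pe
  for (l in seq_len(cfg$n_layers)) {
    lay <- p$dec[[l]]
    # causal self-attention over the cached prefix
    q <- y %*% lay$self$Wq
    state$K[[l]] <- rbind(state$K[[l]], y %*% lay$self$Wk)
    state$V[[l]] <- rbind(state$V[[l]], y %*% lay$self$Wv)
    h <- matrix(0, 1L, d)
    for (hd in seq_len(cfg$n_heads)) {
      idx <- ((hd - 1L) * dh + 1L):(hd * dh)
      s <- tcrossprod(q[, idx, drop = FALSE],
                      state$K[[l]][, idx, drop = FALSE]) / sqrt(dh)
      a <- exp(s - max(s))
      a <- a / sum(a)
      h[, idx] <- a %*% state$V[[l]][, idx, drop = FALSE]
    }
    y <- y + h %*% lay$self$Wo
    # cross-attention against the pre-computed protein keys/values
    q <- y %*% lay$cross$Wq
    h <- matrix(0, 1L, d)
    for (hd in seq_len(cfg$n_heads)) {
      idx <- ((hd - 1L) * dh + 1L):(hd * dh)
      s <- tcrossprod(q[, idx, drop = FALSE],
                      state$ctx$cross[[l]]$K[, idx, drop = FALSE]) / sqrt(dh)
      a <- exp(s - max(s))
      a <- a / sum(a)
      h[, idx] <- a %*% state$ctx$cross[[l]]$V[, idx, drop = FALSE]
    }
    y <- y + h %*% lay$cross$Wo
    f <- ffn_forward(y, lay$ffn)
    y <- y + f$out
  }
  logits <- as.numeric(y %*% p$W_out) + p$b_out
  # the model never emits PAD or BOS
  logits[vocab$index[c(vocab$pad, vocab$bos)]] <- -Inf
  e <- exp(logits - max(logits))
  probs <- e / sum(e)
  names(probs) <- vocab$tokens
  state$t <- t
  list(probs = probs, state = state)
}

#' Next-token distribution for an explicit prefix
#'
#' Convenience wrapper over [decode_init()]/[decode_step()]: feeds the whole
#' prefix (which must begin with BOS) and returns the distribution over the
#' following token.
#'
#' @param model,ctx Model and protein context.
#' @param prefix Character vector of tokens beginning with the BOS token.
#' @return Named probability vector over the vocabulary.
#' @export
next_token_distribution <- function(model, ctx, prefix) {
  vocab <- model_vocab(model)
  if (length(prefix) == 0L || prefix[[1L]] != vocab$bos) {
    stop("prefix must begin with the BOS token ", dQuote(vocab$bos))
  }
  unknown <- setdiff(prefix, vocab$tokens)
  if (length(unknown) > 0L) {
    stop("prefix contains token(s) outside vocabulary: ",
         paste(dQuote(unknown), collapse = ", "))
  }
  state <- decode_init(model, ctx)
  probs <- NULL
  for (tok in prefix) {
    r <- decode_step(model, state, tok)
    probs <- r$probs
    state <- r$state
  }
  probs
}

# Vocabulary accessor shared by real and mock models.
model_vocab <- function(model) {
  model$vocab
}

# -- deterministic table-driven mock --------------------------------------------

#' A table-driven mock prior model
#'
#' A deterministic stand-in for the transformer used throughout the decoder
#' tests: a lookup table maps each token prefix (starting at BOS) to a
#' probability vector over the vocabulary.
#'
#' @param transitions Named list.  Keys are space-joined token prefixes
#'   including the leading BOS (e.g. `"<bos>"`, `"<bos> C"`); values are
#'   named non-negative numeric vectors over chemical tokens and/or EOS,
#'   which are normalised to sum to one.
#' @param tokens Character vector of chemical tokens, in the index order the
#'   vocabulary should use.
#' @param fallback Optional named distribution used for prefixes absent from
#'   `transitions`; if `NULL`, querying an unknown prefix is an error.
#' @param bos,eos,pad Special token spellings.
#' @return A `mock_model`.
#' @export
mock_model <- function(transitions, tokens, fallback = NULL,
                       bos = "<bos>", eos = "<eos>", pad = "<pad>") {
  vocab_tokens <- c(pad, bos, eos, tokens)
  stopifnot(anyDuplicated(vocab_tokens) == 0L)
  vocab <- structure(list(tokens = vocab_tokens,
                          index = stats::setNames(seq_along(vocab_tokens),
                                                  vocab_tokens),
                          bos = bos, eos = eos, pad = pad),
                     class = "smiles_vocab")
  normalise <- function(v, where) {
    stopifnot(is.numeric(v), !is.null(names(v)))
    bad <- setdiff(names(v), c(tokens, eos))
    if (length(bad) > 0L) {
      stop("distribution for ", dQuote(where), " names unknown token(s): ",
           paste(bad, collapse = ", "))
    }
    if (any(v < 0) || sum(v) <= 0) {
      stop("distribution for ", dQuote(where),
           " must be non-negative with positive mass")
    }
    v <- v / sum(v)
    stopifnot(abs(sum(v) - 1) < 1e-9)
    dense <- stats::setNames(numeric(length(vocab_tokens)), vocab_tokens)
    dense[names(v)] <- v
    dense
  }
  transitions <- stats::setNames(
    lapply(names(transitions),
           function(k) normalise(transitions[[k]], k)),
    names(transitions))
  if (!is.null(fallback)) {
    fallback <- normalise(fallback, "<fallback>")
  }
  structure(list(transitions = transitions, fallback = fallback,
                 vocab = vocab),
            class = "mock_model")
}

#' @export
encode.mock_model <- function(model, protein_seq) {
  structure(list(enc_out = NULL, uid = "mock",
                 length = nchar(protein_seq)),
            class = "protein_context")
}

#' @export
decode_init.mock_model <- function(model, ctx) {
  list(prefix = character(0))
}

#' @export
decode_step.mock_model <- function(model, state, token) {
  if (!(token %in% model$vocab$tokens)) {
    stop("token outside vocabulary: ", dQuote(token))
  }
  prefix <- c(state$prefix, token)
  key <- paste(prefix, collapse = " ")
  probs <- model$transitions[[key]] %||% model$fallback
  if (is.null(probs)) {
    stop("mock model has no distribution for prefix ", dQuote(key))
  }
  list(probs = probs, state = list(prefix = prefix))
}
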