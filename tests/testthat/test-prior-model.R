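toy_pairs <- function(n, seed, smiles = NULL) {
  set.seed(seed)
  templates <- smiles %||% template_fixture()
  data.frame(protein_seq = replicate(n, paste(sample(c("A", "M", "K", "V",
                                                       "L", "G", "S", "T"),
                                                     sample(30:60, 1),
                                                     replace = TRUE),
                                              collapse = "")),
             smiles = sample(templates, n, replace = TRUE),
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("mock model returns its table distribution", {
  m <- mock_model(list(`<bos>` = c(C = 1)), tokens = c("C", "O"))
  ctx <- encode(m, "MKV")
  p <- next_token_distribution(m, ctx, "<bos>")
  expect_equal(unname(p[["C"]]), 1)
  expect_equal(sum(p), 1)
  expect_error(next_token_distribution(m, ctx, c("<bos>", "Z")),
               "outside vocabulary")
  expect_error(next_token_distribution(m, ctx, "C"), "BOS")
})

test_that("encoding is deterministic and validates its input", {
  model <- train_toy(toy_pairs(4, 1), toy_transformer_config(n_epochs = 1))
  ctx1 <- encode(model, "MKVLA")
  ctx2 <- encode(model, "MKVLA")
  expect_equal(ctx1$enc_out, ctx2$enc_out)
  expect_error(encode(model, ""), "empty")
  expect_error(encode(model, "MKZ"), "illegal residue")
  long <- paste(rep("A", 301), collapse = "")
  expect_error(encode(model, long), "max_protein_len")
})

test_that("contexts are tied to the model instance that made them", {
  m1 <- train_toy(toy_pairs(4, 1), toy_transformer_config(n_epochs = 1,
                                                          seed = 1))
  m2 <- train_toy(toy_pairs(4, 2), toy_transformer_config(n_epochs = 1,
                                                          seed = 2))
  ctx <- encode(m1, "MKVLA")
  expect_error(decode_init(m2, ctx), "model instance")
})

test_that("next-token distributions normalise over the vocabulary", {
  model <- train_toy(toy_pairs(6, 3), toy_transformer_config(n_epochs = 2))
  ctx <- encode(model, "MKVLAGST")
  vocab <- model$vocab
  prefixes <- list(vocab$bos, c(vocab$bos, "C"), c(vocab$bos, "C", "C"),
                   c(vocab$bos, "c", "1"))
  for (pf in prefixes) {
    p <- next_token_distribution(model, ctx, pf)
    expect_length(p, length(vocab$tokens))
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-6)
    # the model never proposes PAD or BOS
    expect_equal(unname(p[[vocab$pad]]), 0)
    expect_equal(unname(p[[vocab$bos]]), 0)
  }
})

test_that("attention rows are simplex weights", {
  set.seed(5)
  d <- 8L
  X <- matrix(rnorm(5 * d), 5, d)
  p <- mctsmol:::init_attn_params(d)
  for (causal in c(FALSE, TRUE)) {
    a <- mctsmol:::mha_forward(X, X, p, n_heads = 2L, causal = causal)
    for (A in a$cache$A) {
      expect_true(all(A >= 0))
      expect_equal(rowSums(A), rep(1, nrow(A)))
      if (causal) {
        expect_true(all(A[upper.tri(A)] == 0))
      }
    }
  }
})

test_that("analytic gradients agree with finite differences", {
  ns <- asNamespace("mctsmol")
  set.seed(42)
  cfg <- transformer_config(n_layers = 1, d_model = 8, n_heads = 2,
                            d_ff = 12, max_protein_len = 20,
                            max_smiles_len = 10, seed = 3)
  params <- ns$init_params(cfg, n_aa = 21, n_vocab = 7)
  aa_ids <- c(1L, 5L, 3L, 2L)
  sm <- list(input = c(2L, 4L, 5L, 6L), target = c(4L, 5L, 6L, 3L))
  res <- ns$pair_loss_and_grads(params, cfg, aa_ids, sm)
  loss_at <- function(p) {
    ns$pair_loss_and_grads(p, cfg, aa_ids, sm, want_grads = FALSE)$loss
  }
  get_leaf <- function(p, path) Reduce(`[[`, path, p)
  bump <- function(p, path, i, d) {
    if (length(path) == 1L) {
      p[[path[[1L]]]][[i]] <- p[[path[[1L]]]][[i]] + d
    } else {
      p[[path[[1L]]]] <- bump(p[[path[[1L]]]], path[-1L], i, d)
    }
    p
  }
  eps <- 1e-6
  probes <- list(
    list(list("emb_protein"), 5L), list(list("emb_smiles"), 13L),
    list(list("W_out"), 3L), list(list("b_out"), 2L),
    list(list("enc", 1L, "attn", "Wq"), 7L),
    list(list("enc", 1L, "ffn", "b2"), 4L),
    list(list("dec", 1L, "self", "Wk"), 9L),
    list(list("dec", 1L, "cross", "Wv"), 14L))
  for (probe in probes) {
    path <- probe[[1]]
    i <- probe[[2]]
    numeric_grad <- (loss_at(bump(params, path, i, eps)) -
                       loss_at(bump(params, path, i, -eps))) / (2 * eps)
    analytic <- get_leaf(res$grads, path)[[i]]
    expect_equal(analytic, numeric_grad, tolerance = 1e-5)
  }
})

test_that("training lowers the loss and is reproducible", {
  pairs <- toy_pairs(12, 4)
  cfg <- toy_transformer_config(n_epochs = 4, seed = 7)
  m1 <- train_toy(pairs, cfg)
  expect_lt(tail(m1$loss_history, 1), m1$loss_history[["initial"]])
  m2 <- train_toy(pairs, cfg)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_error(train_toy(pairs[1, ], cfg), "at least 2")
  bad <- pairs
  bad$smiles[2] <- "C1CC"
  expect_error(train_toy(bad, cfg), "invalid SMILES")
})

test_that("a degenerate single-ligand corpus is memorised", {
  pairs <- toy_pairs(6, 8, smiles = "CC(=O)O")
  model <- train_toy(pairs, toy_transformer_config(n_epochs = 40, seed = 7))
  ctx <- encode(model, pairs$protein_seq[[1]])
  expect_identical(detokenize_smiles(greedy_decode(model, ctx, 20)),
                   "CC(=O)O")
})

test_that("training shifts probability mass onto the corpus start token", {
  # every ligand starts with "C"; after training P(C | BOS) must be argmax
  pairs <- toy_pairs(10, 9, smiles = c("CCO", "CC(C)O", "CCN", "CC(N)=O"))
  model <- train_toy(pairs, toy_transformer_config(n_epochs = 10, seed = 2))
  ctx <- encode(model, pairs$protein_seq[[1]])
  p <- next_token_distribution(model, ctx, model$vocab$bos)
  expect_identical(names(which.max(p)), "C")
})

test_that("checkpoints round-trip through save/load", {
  model <- train_toy(toy_pairs(4, 10), toy_transformer_config(n_epochs = 1))
  path <- tempfile(fileext = ".rds")
  on.exit(unlink(path))
  save_model(model, path)
  restored <- load_model(path)
  ctx_a <- encode(model, "MKVLA")
  ctx_b <- encode(restored, "MKVLA")
  expect_equal(next_token_distribution(model, ctx_a, model$vocab$bos),
               next_token_distribution(restored, ctx_b,
                                       restored$vocab$bos))
})
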