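test_that("greedy decode follows the argmax path, ties to lowest index", {
  # forced chain C -> C -> O -> EOS
  m <- mock_model(list(`<bos>` = c(C = 1),
                       `<bos> C` = c(C = 0.9, O = 0.1),
                       `<bos> C C` = c(O = 0.6, `<eos>` = 0.4),
                       `<bos> C C O` = c(`<eos>` = 1)),
                  tokens = c("C", "O"))
  ctx <- encode(m, "MKV")
  expect_identical(greedy_decode(m, ctx), c("C", "C", "O"))
  # exact tie: the lower vocabulary index wins deterministically
  tie <- mock_model(list(`<bos>` = c(C = 0.5, O = 0.5),
                         `<bos> C` = c(`<eos>` = 1),
                         `<bos> O` = c(`<eos>` = 1)),
                    tokens = c("C", "O"))
  ctx2 <- encode(tie, "MKV")
  first <- greedy_decode(tie, ctx2)[[1]]
  idx <- tie$vocab$index
  expect_identical(first,
                   names(which.min(idx[c("C", "O")])))
  expect_identical(greedy_decode(tie, ctx2), greedy_decode(tie, ctx2))
})

test_that("greedy decode truncates at max_len", {
  m <- mock_model(list(), tokens = "C", fallback = c(C = 1))
  ctx <- encode(m, "MKV")
  expect_identical(greedy_decode(m, ctx, max_len = 5), rep("C", 5))
})

test_that("beam with k = 1 reproduces greedy token-for-token", {
  for (seed in 1:100) {
    m <- random_mock_model(n_tokens = 3, max_len = 4, seed = seed)
    ctx <- encode(m, "MKV")
    g <- greedy_decode(m, ctx, max_len = 4)
    b <- beam_decode(m, ctx, k = 1, max_len = 4)
    expect_identical(b[[1]]$tokens, g)
  }
})

test_that("beam top result matches exhaustive enumeration for large k", {
  for (seed in 1:50) {
    n_tokens <- sample(2:4, 1)
    max_len <- sample(3:5, 1)
    alpha <- sample(c(0, 0.5, 1), 1)
    m <- random_mock_model(n_tokens = n_tokens, max_len = max_len,
                           seed = 100 + seed)
    ctx <- encode(m, "MKV")
    oracle <- enumerate_best(m, ctx, length_alpha = alpha,
                             max_len = max_len)
    # k at least the number of leaves makes beam exhaustive
    b <- beam_decode(m, ctx, k = (n_tokens + 1)^max_len,
                     length_alpha = alpha, max_len = max_len)
    expect_equal(b[[1]]$score, oracle$score, tolerance = 1e-12)
    expect_identical(b[[1]]$tokens, oracle$tokens)
  }
})

test_that("beam results arrive sorted with self-consistent scores", {
  m <- random_mock_model(n_tokens = 3, max_len = 4, seed = 77)
  ctx <- encode(m, "MKV")
  b <- beam_decode(m, ctx, k = 5, length_alpha = 0.5, max_len = 4)
  expect_lte(length(b), 5)
  scores <- vapply(b, `[[`, numeric(1), "score")
  expect_true(all(diff(scores) <= 1e-12))
  for (cand in b) {
    steps <- if (length(cand$tokens) >= 4) 4 else length(cand$tokens) + 1
    expect_equal(cand$score, cand$logp / steps^0.5, tolerance = 1e-12)
  }
  expect_error(beam_decode(m, ctx, k = 0), "k")
})

test_that("UCB scores match the closed form", {
  node <- mctsmol:::new_tree_node(token = "C", parent = NULL, depth = 1L)
  expect_identical(ucb_score(node, parent_visits = 10), Inf)  # unvisited
  node$n_visits <- 4L
  node$cum_reward <- 6
  # exploitation only: 6/4
  expect_equal(ucb_score(node, parent_visits = 10, c_explore = 0), 1.5)
  # 6/4 + 2 * sqrt(log(10)/4)
  expect_equal(ucb_score(node, parent_visits = 10, c_explore = 2),
               1.5 + 2 * sqrt(log(10) / 4))
})

test_that("MCTS returns the only reachable molecule when forced", {
  m <- mock_model(list(`<bos>` = c(C = 1),
                       `<bos> C` = c(C = 1),
                       `<bos> C C` = c(O = 1),
                       `<bos> C C O` = c(`<eos>` = 1)),
                  tokens = c("C", "O"))
  ctx <- encode(m, "MKV")
  res <- mcts_generate(m, ctx, reward_config(),
                       mcts_config(n_simulations = 10, seed = 1))
  expect_identical(res$smiles, "CCO")
  expect_equal(res$reward$composite,
               compute_reward("CCO", reward_config())$composite)
  expect_identical(res$decoder, "mcts")
})

test_that("MCTS conserves the simulation budget in its tree", {
  m <- random_mock_model(n_tokens = 3, max_len = 4, seed = 5)
  ctx <- encode(m, "MKV")
  cfg <- mcts_config(n_simulations = 60, max_depth = 4, seed = 2)
  res <- mcts_generate(m, ctx, reward_config(), cfg)
  expect_identical(res$simulations_used, 60L)
  expect_identical(res$root$n_visits, 60L)
  max_composite <- 1 + 1 + 1  # weights (1,1,1,0), each component <= 1
  check_tree_invariants(res$root, max_composite)
  expect_true(is_valid_smiles(res$smiles))
})

test_that("MCTS is reproducible under a fixed seed", {
  m <- random_mock_model(n_tokens = 3, max_len = 4, seed = 11)
  ctx <- encode(m, "MKV")
  cfg <- mcts_config(n_simulations = 40, max_depth = 4, seed = 9)
  r1 <- mcts_generate(m, ctx, reward_config(), cfg)
  r2 <- mcts_generate(m, ctx, reward_config(), cfg)
  expect_identical(r1$smiles, r2$smiles)
  expect_equal(r1$reward$composite, r2$reward$composite)
})

test_that("pure exploitation converges to the best enumerable molecule", {
  # tiny space: enumerate all terminal sequences, find the max composite
  m <- random_mock_model(n_tokens = 2, max_len = 3, seed = 21)
  ctx <- encode(m, "MKV")
  vocab <- m$vocab
  chem <- setdiff(vocab$tokens, c(vocab$bos, vocab$eos, vocab$pad))
  seqs <- unlist(lapply(1:3, function(len) {
    grid <- do.call(expand.grid, rep(list(chem), len))
    apply(grid, 1, paste, collapse = "")
  }))
  rcfg <- reward_config()
  best <- max(vapply(unique(seqs),
                     function(s) compute_reward(s, rcfg)$composite,
                     numeric(1)))
  res <- mcts_generate(m, ctx, rcfg,
                       mcts_config(c_explore = 0, n_simulations = 400,
                                   max_depth = 3, seed = 3))
  expect_equal(res$reward$composite, best, tolerance = 1e-12)
})

test_that("MCTS with a validity gate errors when nothing valid is reachable", {
  # the only terminal sequence is "(", never a valid molecule
  m <- mock_model(list(`<bos>` = c(`(` = 1),
                       `<bos> (` = c(`<eos>` = 1)),
                  tokens = "(")
  ctx <- encode(m, "MKV")
  expect_error(mcts_generate(m, ctx, reward_config(),
                             mcts_config(n_simulations = 5, seed = 1)),
               "valid")
})

test_that("higher exploration broadens the visited tree", {
  m <- random_mock_model(n_tokens = 3, max_len = 4, seed = 31)
  ctx <- encode(m, "MKV")
  distinct_visited <- function(c_explore) {
    res <- mcts_generate(m, ctx, reward_config(),
                         mcts_config(c_explore = c_explore,
                                     n_simulations = 80, max_depth = 4,
                                     seed = 4))
    visited <- vapply(res$root$children, function(ch) ch$n_visits > 0,
                      logical(1))
    sum(visited)
  }
  expect_gte(distinct_visited(5), distinct_visited(0))
})
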