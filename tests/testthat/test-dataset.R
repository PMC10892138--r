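rec <- function(organism = "Homo sapiens", ic50 = NA, kd = NA, ec50 = NA,
                smiles = "CCO", protein = "MKVLA") {
  data.frame(organism = organism, ic50_nM = ic50, kd_nM = kd, ec50_nM = ec50,
             smiles = smiles, protein_seq = protein, stringsAsFactors = FALSE)
}

test_that("filter applies the measurement priority chain", {
  # potent IC50 passes
  expect_identical(nrow(filter_binding_records(rec(ic50 = 50))), 1L)
  # failing IC50 masks a potent Kd: record is dropped
  expect_identical(nrow(filter_binding_records(rec(ic50 = 500, kd = 5))), 0L)
  # missing IC50 falls through to Kd
  expect_identical(nrow(filter_binding_records(rec(kd = 5))), 1L)
  # missing IC50 and Kd falls through to EC50
  expect_identical(nrow(filter_binding_records(rec(ec50 = 99.9))), 1L)
  # all measurements missing: dropped
  expect_identical(nrow(filter_binding_records(rec())), 0L)
  # threshold is strict
  expect_identical(nrow(filter_binding_records(rec(ic50 = 100))), 0L)
  expect_identical(nrow(filter_binding_records(rec(ic50 = 99.999))), 1L)
})

test_that("filter enforces organism and SMILES presence", {
  expect_identical(nrow(filter_binding_records(rec(organism = "Mus musculus",
                                                   ic50 = 1))), 0L)
  expect_identical(nrow(filter_binding_records(rec(organism = NA,
                                                   ic50 = 1))), 0L)
  expect_identical(nrow(filter_binding_records(rec(smiles = NA,
                                                   ic50 = 1))), 0L)
  expect_identical(nrow(filter_binding_records(rec(smiles = "",
                                                   ic50 = 1))), 0L)
  expect_error(filter_binding_records(data.frame(smiles = "CCO")),
               "missing column")
})

test_that("filter matches a brute-force restatement on random records", {
  for (seed in 1:4) {
    records <- random_records(250, seed)
    kept <- filter_binding_records(records)
    oracle_idx <- brute_force_filter(records)
    expect_identical(kept$smiles, records$smiles[oracle_idx])
    expect_identical(kept$ic50_nM, records$ic50_nM[oracle_idx])
    counts <- attr(kept, "filter_counts")
    expect_identical(unname(counts[["kept"]]), length(oracle_idx))
    expect_identical(unname(counts[["input"]]), 250L)
  }
})

test_that("filtering is idempotent and order-preserving", {
  records <- random_records(200, 9)
  once <- filter_binding_records(records)
  twice <- filter_binding_records(once)
  expect_identical(once$smiles, twice$smiles)
  expect_identical(nrow(once), nrow(twice))
  # kept rows appear in their original relative order
  kept_idx <- brute_force_filter(records)
  expect_identical(once$protein_seq, records$protein_seq[kept_idx])
})

test_that("malformed negative potencies are dropped, not fatal", {
  bad <- rec(ic50 = -5)
  expect_identical(nrow(filter_binding_records(bad)), 0L)
  counts <- attr(filter_binding_records(bad), "filter_counts")
  expect_identical(unname(counts[["malformed"]]), 1L)
})

test_that("pair_dataset canonicalizes ligands and counts uniques", {
  records <- rbind(rec(ic50 = 1, smiles = "OCC"),
                   rec(ic50 = 1, smiles = "CCO", protein = "MKVLAG"))
  ds <- pair_dataset(records)
  expect_identical(ds$pairs$smiles, rep(canonicalize_smiles("CCO"), 2))
  expect_identical(ds$n_unique_ligands, 1L)
  expect_identical(ds$n_unique_proteins, 2L)
  expect_error(pair_dataset(records[0, ]), "no records")
})

test_that("train/test split partitions exactly and reproducibly", {
  records <- random_records(300, 3)
  kept <- filter_binding_records(records)
  kept <- kept[!is.na(kept$smiles) & kept$smiles != "", , drop = FALSE]
  ds <- pair_dataset(kept)
  n <- nrow(ds$pairs)
  sp <- split_train_test(ds, train_frac = 0.7, seed = 5)
  expect_identical(nrow(sp$train$pairs), as.integer(round(0.7 * n)))
  expect_identical(nrow(sp$train$pairs) + nrow(sp$test$pairs), n)
  # partition: multiset union of rows equals the input
  key <- function(p) sort(paste(p$protein_seq, p$smiles))
  expect_identical(sort(c(key(sp$train$pairs), key(sp$test$pairs))),
                   key(ds$pairs))
  sp2 <- split_train_test(ds, train_frac = 0.7, seed = 5)
  expect_identical(sp$train$pairs, sp2$train$pairs)
  sp3 <- split_train_test(ds, train_frac = 0.7, seed = 6)
  expect_false(identical(sp$train$pairs, sp3$train$pairs))
})

test_that("splitting leaves the caller's RNG state untouched", {
  ds <- pair_dataset(rec(ic50 = rep(1, 10),
                         protein = paste0("MKVLA", LETTERS[1:10])))
  set.seed(123)
  before <- .Random.seed
  split_train_test(ds, seed = 4)
  expect_identical(.Random.seed, before)
})

test_that("synthetic generator produces the requested failure count", {
  for (ff in c(0, 0.1, 0.37)) {
    records <- generate_synthetic_pairs(120, seed = 2, fail_fraction = ff)
    expect_identical(nrow(records), 120L)
    kept <- filter_binding_records(records)
    expect_identical(nrow(kept), 120L - as.integer(floor(120 * ff)))
  }
})

test_that("synthetic records are valid, deterministic, and well-formed", {
  a <- generate_synthetic_pairs(40, seed = 7)
  b <- generate_synthetic_pairs(40, seed = 7)
  expect_identical(a, b)
  c <- generate_synthetic_pairs(40, seed = 8)
  expect_false(identical(a, c))
  expect_true(all(is_valid_smiles(a$smiles)))
  expect_true(all(nchar(a$protein_seq) >= 50 & nchar(a$protein_seq) <= 300))
  expect_true(all(grepl("^[A-WY]+$", a$protein_seq)))
  expect_identical(names(a), c("organism", "ic50_nM", "kd_nM", "ec50_nM",
                               "smiles", "protein_seq"))
})

test_that("synthetic failures exercise the priority chain, not just any-of", {
  # with enough failing records, at least one must be the masked-Kd case:
  # failing IC50 with a potent Kd behind it
  records <- generate_synthetic_pairs(400, seed = 3, fail_fraction = 0.5)
  masked <- !is.na(records$ic50_nM) & records$ic50_nM >= 100 &
    !is.na(records$kd_nM) & records$kd_nM < 100
  expect_gt(sum(masked), 0)
  expect_identical(nrow(filter_binding_records(records[masked, ,
                                                       drop = FALSE])), 0L)
})

test_that("binding TSV reader maps BindingDB headers and qualifiers", {
  path <- withr::local_tempfile(fileext = ".tsv")
  header <- paste("Target Source Organism According to Curator or DataSource",
                  "IC50 (nM)", "Kd (nM)", "EC50 (nM)", "Ligand SMILES",
                  "BindingDB Target Chain Sequence", sep = "\t")
  rows <- c(paste("Homo sapiens", "12.5", "", "", "CCO", "MKVLA", sep = "\t"),
            paste("Homo sapiens", ">1000", "5", "", "CCN", "MKVLA",
                  sep = "\t"))
  writeLines(c(header, rows), path)
  records <- read_binding_tsv(path)
  expect_identical(records$ic50_nM, c(12.5, 1000))
  expect_identical(records$kd_nM, c(NA, 5))
  kept <- filter_binding_records(records)
  expect_identical(kept$smiles, "CCO")  # row 2 fails on its (qualified) IC50
})

test_that("pairs round-trip to .smi and FASTA", {
  ds <- pair_dataset(rec(ic50 = c(1, 2), smiles = c("CCO", "CCN"),
                         protein = c("MKVLA", "MKVLA")))
  smi <- withr::local_tempfile(fileext = ".smi")
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_pairs(ds, smi, fa)
  expect_identical(read_smi(smi)$smiles, ds$pairs$smiles)
  prot <- read_protein_fasta(fa)
  expect_identical(unname(prot), "MKVLA")  # deduplicated
})
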