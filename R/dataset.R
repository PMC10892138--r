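# BindingDB-style dataset handling -------------------------------------------------
#
# A binding record is one measured protein-ligand interaction: the target
# organism, up to three potency measurements (IC50, Kd, EC50; nM), the ligand
# SMILES and the target amino-acid sequence.  Records are filtered down to
# potent human interactions before pairing, and pairs are split at random
# into train/test subsets.

.BINDING_COLS <- c("organism", "ic50_nM", "kd_nM", "ec50_nM", "smiles",
                   "protein_seq")

#' Filter binding records to potent human protein-ligand pairs
#'
#' Keeps a record iff (i) the organism is `"Homo sapiens"`, (ii) a SMILES is
#' present, and (iii) the highest-priority potency measurement that is
#' present is below 100 nM, in the priority order IC50, then Kd, then EC50.
#' The rule is a priority chain, not an any-of: a present-but-failing IC50
#' excludes the record even if a potent Kd exists.  Records with all three
#' measurements missing are dropped.  Input order is preserved, and filtering
#' is idempotent.
#'
#' @param records Data frame with columns `organism`, `ic50_nM`, `kd_nM`,
#'   `ec50_nM` (non-negative numerics, `NA` when missing), `smiles` and
#'   `protein_seq`.
#' @param threshold_nM Potency cutoff; default 100 nM (strict `<`).
#' @return The kept rows, with a `"filter_counts"` attribute recording how
#'   many rows each criterion removed.
#' @export
filter_binding_records <- function(records, threshold_nM = 100) {
  records <- as.data.frame(records)
  missing_cols <- setdiff(.BINDING_COLS, names(records))
  if (length(missing_cols) > 0L) {
    stop("records are missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  n <- nrow(records)
  # malformed rows (negative potencies) are dropped, not fatal
  malformed <- rep(FALSE, n)
  for (col in c("ic50_nM", "kd_nM", "ec50_nM")) {
    v <- records[[col]]
    malformed <- malformed | (!is.na(v) & v < 0)
  }
  human <- !is.na(records$organism) & records$organism == "Homo sapiens"
  has_smiles <- !is.na(records$smiles) & nchar(records$smiles) > 0L
  first_present <- ifelse(!is.na(records$ic50_nM), records$ic50_nM,
                          ifelse(!is.na(records$kd_nM), records$kd_nM,
                                 records$ec50_nM))
  potent <- !is.na(first_present) & first_present < threshold_nM
  keep <- !malformed & human & has_smiles & potent
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_counts") <- c(input = n,
                                  malformed = sum(malformed),
                                  not_human = sum(!human & !malformed),
                                  no_smiles = sum(!has_smiles & human &
                                                    !malformed),
                                  not_potent = sum(!potent & has_smiles &
                                                     human & !malformed),
                                  kept = sum(keep))
  out
}

#' Assemble a protein-ligand pair dataset
#'
#' Canonicalizes every ligand SMILES (all must be valid) and counts unique
#' proteins and ligands.  Duplicate pairs are retained.
#'
#' @param records Filtered binding records, or any data frame with `smiles`
#'   and `protein_seq` columns.
#' @return A `pair_dataset`: list with `pairs` (data.frame of `protein_seq`,
#'   `smiles`), `n_unique_proteins`, `n_unique_ligands`.
#' @export
pair_dataset <- function(records) {
  records <- as.data.frame(records)
  stopifnot(all(c("smiles", "protein_seq") %in% names(records)))
  if (nrow(records) == 0L) {
    stop("no records to pair")
  }
  canonical <- canonicalize_smiles(records$smiles)
  pairs <- data.frame(protein_seq = records$protein_seq, smiles = canonical,
                      stringsAsFactors = FALSE)
  structure(list(pairs = pairs,
                 n_unique_proteins = length(unique(pairs$protein_seq)),
                 n_unique_ligands = length(unique(pairs$smiles))),
            class = "pair_dataset")
}

#' @export
print.pair_dataset <- function(x, ...) {
  cat("<pair_dataset> ", nrow(x$pairs), " pairs (",
      x$n_unique_proteins, " unique proteins, ",
      x$n_unique_ligands, " unique ligands)\n", sep = "")
  invisible(x)
}

#' Random train/test split of a pair dataset
#'
#' An exact partition: `round(n * train_frac)` pairs go to the training set,
#' the remainder to the test set.  Reproducible given `seed`; the caller's
#' RNG state is left untouched.
#'
#' @param ds A [pair_dataset()].
#' @param train_frac Fraction in (0, 1); the published split is 0.7.
#' @param seed Integer seed.
#' @return `list(train =, test =)` of `pair_dataset`s.
#' @export
split_train_test <- function(ds, train_frac = 0.7, seed = 1L) {
  stopifnot(inherits(ds, "pair_dataset"),
            is.numeric(train_frac), train_frac > 0, train_frac < 1)
  n <- nrow(ds$pairs)
  if (n < 2L) {
    stop("dataset must contain at least 2 pairs to split")
  }
  n_train <- round(n * train_frac)
  n_train <- min(max(n_train, 1L), n - 1L)
  idx <- with_seed(seed, sample.int(n, n_train))
  list(train = pair_dataset(ds$pairs[idx, , drop = FALSE]),
       test = pair_dataset(ds$pairs[-idx, , drop = FALSE]))
}

#' Generate synthetic binding records
#'
#' A download-free stand-in for a BindingDB extract: ligands are drawn from
#' the packaged list of small, pre-validated SMILES templates and targets are
#' random 50-300-residue protein strings.  Exactly `floor(n * fail_fraction)`
#' records violate one filtering criterion each (wrong organism, missing
#' SMILES, or first-present potency at/above 100 nM); the remainder pass.
#' Passing records vary which measurement carries the potency (IC50, Kd after
#' a missing IC50, or EC50 after both missing) and may carry non-potent
#' values in lower-priority fields, which the priority-chain filter must
#' ignore.
#'
#' @param n Number of records.
#' @param seed Integer seed; the same seed reproduces the same records.
#' @param fail_fraction Fraction in \[0, 1) of records built to fail the
#'   filter.
#' @return A data frame of binding records (see [filter_binding_records()]).
#' @export
generate_synthetic_pairs <- function(n, seed = 1L, fail_fraction = 0) {
  stopifnot(n >= 1, fail_fraction >= 0, fail_fraction < 1)
  templates <- ligand_templates()
  aa20 <- setdiff(.AA_LETTERS, "X")
  with_seed(seed, {
    random_protein <- function() {
      paste(sample(aa20, sample(50:300, 1L), replace = TRUE), collapse = "")
    }
    n_fail <- floor(n * fail_fraction)
    fail_idx <- if (n_fail > 0L) sample.int(n, n_fail) else integer(0)
    fail_mode <- stats::setNames(rep(NA_character_, n), NULL)
    fail_mode[fail_idx] <- rep(c("organism", "smiles", "potency"),
                               length.out = n_fail)
    records <- lapply(seq_len(n), function(i) {
      rec <- list(organism = "Homo sapiens",
                  ic50_nM = NA_real_, kd_nM = NA_real_, ec50_nM = NA_real_,
                  smiles = sample(templates, 1L),
                  protein_seq = random_protein())
      mode <- fail_mode[[i]]
      if (is.na(mode)) {
        pattern <- sample(c("ic50", "kd", "ec50"), 1L)
        potent <- stats::runif(1L, 0.1, 99.9)
        if (pattern == "ic50") {
          rec$ic50_nM <- potent
          # non-potent noise in a lower-priority field must not matter
          if (stats::runif(1L) < 0.3) {
            rec$kd_nM <- stats::runif(1L, 100, 10000)
          }
        } else if (pattern == "kd") {
          rec$kd_nM <- potent
          if (stats::runif(1L) < 0.3) {
            rec$ec50_nM <- stats::runif(1L, 100, 10000)
          }
        } else {
          rec$ec50_nM <- potent
        }
      } else if (mode == "organism") {
        rec$organism <- sample(c("Mus musculus", "Rattus norvegicus"), 1L)
        rec$ic50_nM <- stats::runif(1L, 0.1, 99.9)
      } else if (mode == "smiles") {
        rec$smiles <- NA_character_
        rec$ic50_nM <- stats::runif(1L, 0.1, 99.9)
      } else { # potency: first-present measurement fails
        which_fail <- sample(c("ic50_high", "all_missing", "masked_kd"), 1L)
        if (which_fail == "ic50_high") {
          rec$ic50_nM <- stats::runif(1L, 100, 10000)
        } else if (which_fail == "masked_kd") {
          # potent Kd hidden behind a failing IC50: priority chain drops it
          rec$ic50_nM <- stats::runif(1L, 100, 10000)
          rec$kd_nM <- stats::runif(1L, 0.1, 99.9)
        }
        # "all_missing": leave every measurement NA
      }
      rec
    })
    out <- do.call(rbind, lapply(records, as.data.frame,
                                 stringsAsFactors = FALSE))
    rownames(out) <- NULL
    out[, .BINDING_COLS]
  })
}

# The packaged small-molecule SMILES templates used by the synthetic
# generator (one per line, pre-validated).
ligand_templates <- function() {
  path <- system.file("extdata", "ligand_templates.smi", package = "mctsmol")
  if (path == "") {
    stop("ligand_templates.smi not found; is the package installed?")
  }
  read_smi(path)$smiles
}

# TSV / FASTA interfaces ------------------------------------------------------------

#' Read BindingDB-style TSV records
#'
#' Maps tabular columns onto binding-record fields.  Potency columns may
#' carry `>`/`<` qualifiers, which are stripped before numeric coercion;
#' values are assumed to already be in nM.
#'
#' @param path TSV file path.
#' @param col_map Named character vector mapping record fields to column
#'   names in the file; defaults follow BindingDB's export headers.
#' @return A data frame of binding records.
#' @export
read_binding_tsv <- function(path,
                             col_map = c(
                               organism = "Target Source Organism According to Curator or DataSource",
                               ic50_nM = "IC50 (nM)",
                               kd_nM = "Kd (nM)",
                               ec50_nM = "EC50 (nM)",
                               smiles = "Ligand SMILES",
                               protein_seq = "BindingDB Target Chain Sequence")) {
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "")
  missing_cols <- setdiff(unname(col_map), names(raw))
  if (length(missing_cols) > 0L) {
    stop("TSV is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  num <- function(x) suppressWarnings(as.numeric(gsub("^[<>~= ]+", "", x)))
  data.frame(organism = as.character(raw[[col_map[["organism"]]]]),
             ic50_nM = num(raw[[col_map[["ic50_nM"]]]]),
             kd_nM = num(raw[[col_map[["kd_nM"]]]]),
             ec50_nM = num(raw[[col_map[["ec50_nM"]]]]),
             smiles = as.character(raw[[col_map[["smiles"]]]]),
             protein_seq = as.character(raw[[col_map[["protein_seq"]]]]),
             stringsAsFactors = FALSE)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file path.
#' @return Named character vector of amino-acid sequences.
#' @export
read_protein_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(seqs), names(seqs))
}

#' Write a pair dataset's ligands and proteins to disk
#'
#' @param ds A [pair_dataset()].
#' @param smi_path Output `.smi` of ligand SMILES.
#' @param fasta_path Output FASTA of (deduplicated) protein sequences.
#' @return Invisibly, the two paths.
#' @export
write_pairs <- function(ds, smi_path, fasta_path) {
  stopifnot(inherits(ds, "pair_dataset"))
  write_smi(ds$pairs$smiles, smi_path)
  prot <- unique(ds$pairs$protein_seq)
  set <- Biostrings::AAStringSet(prot)
  names(set) <- paste0("protein_", seq_along(prot))
  Biostrings::writeXStringSet(set, fasta_path)
  invisible(c(smi = smi_path, fasta = fasta_path))
}
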