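# Reward composition -------------------------------------------------------------
#
# Four per-molecule reward components drive the tree search: chemical
# validity (0/1), Rule-of-Five adherence (0/1), QED (in [0,1]) and,
# optionally, a docking affinity obtained from an external program.  They
# combine as a weighted sum with a hard validity gate: an invalid SMILES
# scores zero outright, so the search can never be paid for exploring
# unparseable strings.  Affinity (kcal/mol, lower is better, unbounded) is
# made commensurable with the other terms by a linear clip against a floor:
# component = clip(affinity / floor, 0, 1), so a score at or below the floor
# earns the full 1.0.

#' Reward configuration
#'
#' @param weight_validity,weight_ro5,weight_qed,weight_affinity Non-negative
#'   component weights; at least one must be positive.  Defaults (1, 1, 1, 0)
#'   keep docking out of the loop.
#' @param affinity_floor Docking score (kcal/mol, negative) mapped to an
#'   affinity component of 1.0.
#' @param validity_gate If `TRUE` (default) an invalid molecule scores a
#'   composite of exactly 0 regardless of weights.
#' @return A `reward_config`.
#' @export
reward_config <- function(weight_validity = 1, weight_ro5 = 1,
                          weight_qed = 1, weight_affinity = 0,
                          affinity_floor = -12, validity_gate = TRUE) {
  w <- c(weight_validity, weight_ro5, weight_qed, weight_affinity)
  stopifnot(is.numeric(w), all(w >= 0), is.numeric(affinity_floor),
            is.logical(validity_gate))
  if (sum(w) <= 0) {
    stop("at least one reward weight must be positive")
  }
  if (affinity_floor >= 0) {
    stop("affinity_floor must be negative (kcal/mol)")
  }
  structure(list(weight_validity = weight_validity,
                 weight_ro5 = weight_ro5, weight_qed = weight_qed,
                 weight_affinity = weight_affinity,
                 affinity_floor = affinity_floor,
                 validity_gate = isTRUE(validity_gate)),
            class = "reward_config")
}

#' Score one molecule
#'
#' Evaluates the reward components for a candidate SMILES and combines them
#' into the composite scalar used during back-propagation.  Invalid SMILES
#' are an expected input and score zero (never an error); a configured but
#' failing affinity scorer, by contrast, raises — a docking failure must
#' never be silently scored as zero affinity.
#'
#' @param text Candidate SMILES string (possibly invalid or empty).
#' @param config A [reward_config()].
#' @param scorer An affinity scorer ([mock_affinity_scorer()] or
#'   [vina_affinity_scorer()]), or `NULL` to omit the affinity term.
#' @return A `reward_vector`: list with `validity`, `ro5`, `qed`,
#'   `affinity_kcal` (`NA` when unscored) and `composite`.
#' @export
compute_reward <- function(text, config = reward_config(), scorer = NULL) {
  stopifnot(inherits(config, "reward_config"),
            is.character(text), length(text) == 1L)
  valid <- !is.na(text) && is_valid_smiles(text)
  if (!valid) {
    return(structure(list(validity = 0, ro5 = 0, qed = 0,
                          affinity_kcal = NA_real_, composite = 0,
                          smiles = text),
                     class = "reward_vector"))
  }
  desc <- compute_descriptors(text)
  ro5 <- as.numeric(check_ro5(desc)$passes)
  qed <- compute_qed(text)
  composite <- config$weight_validity * 1 +
    config$weight_ro5 * ro5 +
    config$weight_qed * qed
  affinity <- NA_real_
  if (!is.null(scorer) && config$weight_affinity > 0) {
    affinity <- score_affinity(text, scorer)
    component <- min(max(affinity / config$affinity_floor, 0), 1)
    composite <- composite + config$weight_affinity * component
  }
  structure(list(validity = 1, ro5 = ro5, qed = qed,
                 affinity_kcal = affinity, composite = composite,
                 smiles = text),
            class = "reward_vector")
}

#' @export
print.reward_vector <- function(x, ...) {
  cat("<reward_vector> validity=", x$validity, " ro5=", x$ro5,
      " qed=", round(x$qed, 3),
      if (!is.na(x$affinity_kcal)) paste0(" affinity=", x$affinity_kcal),
      " composite=", round(x$composite, 4), "\n", sep = "")
  invisible(x)
}

# Affinity scorers ----------------------------------------------------------------

#' Mock affinity scorer
#'
#' Injects an arbitrary function as the docking stage, so reward composition
#' and search behaviour can be tested without an external docking program.
#'
#' @param fun `function(smiles) -> numeric` docking score in kcal/mol.
#' @return An `affinity_scorer`.
#' @export
mock_affinity_scorer <- function(fun) {
  stopifnot(is.function(fun))
  structure(list(fun = fun),
            class = c("mock_affinity_scorer", "affinity_scorer"))
}

#' External docking affinity scorer
#'
#' Adapter around an external docking executable (e.g. AutoDock Vina).  The
#' command template is expanded with the placeholders `{ligand}` (a file
#' containing the candidate SMILES), `{receptor}`, `{cx}`, `{cy}`, `{cz}`,
#' `{sx}`, `{sy}`, `{sz}` (search-box centre and size in Angstrom), `{seed}`
#' and `{out}`.  The command must write candidate scores (kcal/mol), one per
#' line, to `{out}`; the best (lowest) is returned.  Any ligand preparation
#' the program needs (e.g. 3D embedding to PDBQT) belongs inside the wrapped
#' command.
#'
#' @param receptor Path to the receptor structure file, passed through
#'   verbatim.
#' @param box_center,box_size Numeric length-3 vectors, Angstrom.
#' @param command_template Shell command with the placeholders above.
#' @param executable Name/path checked for existence before any run.
#' @param seed Seed forwarded to the external program.
#' @return An `affinity_scorer`.
#' @export
vina_affinity_scorer <- function(receptor, box_center, box_size,
                                 command_template, executable = "vina",
                                 seed = 0L) {
  stopifnot(length(box_center) == 3L, length(box_size) == 3L,
            is.numeric(box_center), is.numeric(box_size))
  if (any(box_size <= 0)) {
    stop("docking box sizes must be positive")
  }
  structure(list(receptor = receptor, box_center = box_center,
                 box_size = box_size, command_template = command_template,
                 executable = executable, seed = as.integer(seed)),
            class = c("vina_affinity_scorer", "affinity_scorer"))
}

#' Docking score for one molecule
#'
#' @param text A valid SMILES string.
#' @param scorer An `affinity_scorer`.
#' @return Best (lowest) docking score in kcal/mol.
#' @export
score_affinity <- function(text, scorer) {
  UseMethod("score_affinity", scorer)
}

#' @export
score_affinity.mock_affinity_scorer <- function(text, scorer) {
  val <- scorer$fun(text)
  stopifnot(is.numeric(val), length(val) == 1L, is.finite(val))
  val
}

#' @export
score_affinity.vina_affinity_scorer <- function(text, scorer) {
  if (Sys.which(scorer$executable) == "" && !file.exists(scorer$executable)) {
    stop("docking executable not found: '", scorer$executable,
         "' (configuration error)")
  }
  if (!is_valid_smiles(text)) {
    stop("cannot dock an invalid SMILES: ", dQuote(text))
  }
  ligand <- tempfile("ligand-", fileext = ".smi")
  out <- tempfile("docking-", fileext = ".out")
  on.exit(unlink(c(ligand, out)), add = TRUE)
  writeLines(text, ligand)
  subst <- c("{ligand}" = ligand, "{receptor}" = scorer$receptor,
             "{cx}" = scorer$box_center[[1L]],
             "{cy}" = scorer$box_center[[2L]],
             "{cz}" = scorer$box_center[[3L]],
             "{sx}" = scorer$box_size[[1L]],
             "{sy}" = scorer$box_size[[2L]],
             "{sz}" = scorer$box_size[[3L]],
             "{seed}" = scorer$seed, "{out}" = out)
  cmd <- scorer$command_template
  for (key in names(subst)) {
    cmd <- gsub(key, subst[[key]], cmd, fixed = TRUE)
  }
  output <- suppressWarnings(system(cmd, intern = TRUE))
  status <- attr(output, "status") %||% 0L
  if (!identical(as.integer(status), 0L)) {
    stop("docking command failed (exit ", status, "):\n",
         paste(output, collapse = "\n"))
  }
  if (!file.exists(out)) {
    stop("docking command wrote no output file:\n",
         paste(output, collapse = "\n"))
  }
  scores <- suppressWarnings(as.numeric(readLines(out, warn = FALSE)))
  scores <- scores[is.finite(scores)]
  if (length(scores) == 0L) {
    stop("docking output contained no numeric scores:\n",
         paste(output, collapse = "\n"))
  }
  min(scores)
}
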