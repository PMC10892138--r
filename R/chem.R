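# SMILES primitives ------------------------------------------------------------

# Token grammar, longest-match first: bracket atoms, two-letter halogens,
# %nn ring-closure labels, organic-subset atoms (aliphatic and aromatic),
# ring digits, bonds, branches and stereo marks.
.smiles_single_tokens <- c("B", "C", "N", "O", "P", "S", "F", "I",
                           "b", "c", "n", "o", "p", "s",
                           as.character(0:9),
                           "-", "=", "#", "$", ":", "/", "\\", "(", ")", ".")

#' Tokenize a SMILES string
#'
#' Splits a SMILES string into chemically meaningful tokens: bracket atoms
#' (`[N+]`, `[nH]`, ...), two-letter halogens (`Cl`, `Br`), `%nn` ring-bond
#' labels, organic-subset atoms, ring-closure digits, bond symbols,
#' parentheses and stereo slashes.  Concatenating the returned tokens always
#' reproduces the input exactly.
#'
#' @param text A single non-empty SMILES string.
#' @param vocab Optional [smiles_vocabulary()]; when supplied, any token not
#'   in the vocabulary raises an error.
#' @return Character vector of tokens.
#' @examples
#' \dontrun{
#' tokenize_smiles("CCl")  # "C" "Cl"
#' }
#' @export
tokenize_smiles <- function(text, vocab = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  if (nchar(text) == 0L) {
    stop("cannot tokenize an empty SMILES string")
  }
  if (grepl("[[:space:]]", text)) {
    stop("SMILES strings must not contain whitespace: ", dQuote(text))
  }
  n <- nchar(text)
  tokens <- character(0)
  i <- 1L
  while (i <= n) {
    ch <- substr(text, i, i)
    if (ch == "[") {
      close <- regexpr("]", substr(text, i, n), fixed = TRUE)
      if (close < 0L) {
        stop("unclosed bracket atom at position ", i, " in ", dQuote(text))
      }
      tok <- substr(text, i, i + close - 1L)
    } else if (substr(text, i, i + 1L) %in% c("Cl", "Br")) {
      tok <- substr(text, i, i + 1L)
    } else if (ch == "%") {
      tok <- substr(text, i, i + 2L)
      if (!grepl("^%[0-9]{2}$", tok)) {
        stop("malformed %nn ring label at position ", i, " in ", dQuote(text))
      }
    } else if (ch %in% .smiles_single_tokens) {
      tok <- ch
    } else {
      stop("unknown SMILES character ", dQuote(ch), " at position ", i,
           " in ", dQuote(text))
    }
    tokens <- c(tokens, tok)
    i <- i + nchar(tok)
  }
  if (!is.null(vocab)) {
    unknown <- setdiff(tokens, vocab$tokens)
    if (length(unknown) > 0L) {
      stop("token(s) outside vocabulary: ", paste(unknown, collapse = ", "))
    }
  }
  tokens
}

#' Reassemble a SMILES string from tokens
#'
#' Inverse of [tokenize_smiles()]: special (BOS/EOS/PAD) tokens are dropped,
#' chemical tokens are concatenated.
#'
#' @param tokens Character vector of tokens.
#' @param vocab Optional vocabulary whose specials are removed first.
#' @return A SMILES string (possibly empty).
#' @export
detokenize_smiles <- function(tokens, vocab = NULL) {
  if (!is.null(vocab)) {
    tokens <- tokens[!(tokens %in% c(vocab$bos, vocab$eos, vocab$pad))]
  }
  paste(tokens, collapse = "")
}

#' Build a SMILES token vocabulary
#'
#' Collects the token set of a SMILES corpus and prepends the three special
#' tokens (PAD, BOS, EOS).  The token/index map is bijective by construction
#' and is frozen into any model trained with it.
#'
#' @param smiles Character vector of SMILES strings (the training corpus).
#' @param bos,eos,pad Special token spellings; they must not collide with
#'   chemical tokens.
#' @return An object of class `smiles_vocab` with elements `tokens` (ordered
#'   token vector, specials first), `index` (named integer lookup), and the
#'   three special spellings.
#' @export
smiles_vocabulary <- function(smiles, bos = "<bos>", eos = "<eos>",
                              pad = "<pad>") {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  specials <- c(pad, bos, eos)
  if (anyDuplicated(specials) > 0L) {
    stop("special tokens must be distinct")
  }
  chem_tokens <- sort(unique(unlist(lapply(smiles, tokenize_smiles))))
  if (any(specials %in% chem_tokens)) {
    stop("special tokens collide with chemical tokens")
  }
  tokens <- c(specials, chem_tokens)
  vocab <- list(tokens = tokens,
                index = stats::setNames(seq_along(tokens), tokens),
                bos = bos, eos = eos, pad = pad)
  class(vocab) <- "smiles_vocab"
  vocab
}

#' @export
print.smiles_vocab <- function(x, ...) {
  cat("<smiles_vocab> ", length(x$tokens), " tokens (",
      length(x$tokens) - 3L, " chemical + BOS/EOS/PAD)\n", sep = "")
  invisible(x)
}

#' @export
length.smiles_vocab <- function(x) length(x$tokens)

#' Is a string a valid SMILES?
#'
#' A string is valid iff it is non-empty, contains no whitespace, and parses
#' to a sanitizable molecule under RDKit's default sanitization.  Never
#' raises on bad input.
#'
#' @param text Character vector of candidate SMILES.
#' @return Logical vector.
#' @export
is_valid_smiles <- function(text) {
  if (length(text) == 0L) {
    return(logical(0))
  }
  stopifnot(is.character(text))
  text[is.na(text)] <- ""
  chem_props(text)$valid
}

#' Canonicalize SMILES
#'
#' Maps every valid encoding of a molecule to RDKit's unique canonical
#' SMILES.  Idempotent; errors on invalid input.
#'
#' @param text Character vector of valid SMILES.
#' @return Character vector of canonical SMILES.
#' @export
canonicalize_smiles <- function(text) {
  props <- chem_props(text)
  if (any(!props$valid)) {
    bad <- text[!props$valid]
    stop("cannot canonicalize invalid SMILES: ",
         paste(dQuote(utils::head(bad, 5L)), collapse = ", "))
  }
  props$canonical
}

#' Molecular descriptors for the Rule-of-Five and property reports
#'
#' Computes, per molecule: average-isotope molecular weight (Da), Crippen
#' logP, Lipinski hydrogen-bond donors (OH + NH count) and acceptors
#' (N + O count), rotatable-bond count and ring count.
#'
#' @param text Character vector of valid SMILES.
#' @return A `data.frame` with one row per input and columns `smiles`, `mw`,
#'   `logp`, `hbd`, `hba`, `rotatable_bonds`, `rings`.
#' @export
compute_descriptors <- function(text) {
  props <- chem_props(text)
  if (any(!props$valid)) {
    bad <- text[!props$valid]
    stop("cannot compute descriptors for invalid SMILES: ",
         paste(dQuote(utils::head(bad, 5L)), collapse = ", "))
  }
  props[, c("smiles", "mw", "logp", "hbd", "hba", "rotatable_bonds", "rings")]
}

#' Lipinski's Rule of Five check
#'
#' Applies the four enumerated oral-bioavailability criteria with inclusive
#' thresholds: MW \eqn{\le} 500 Da, logP \eqn{\le} 5, HBD \eqn{\le} 5,
#' HBA \eqn{\le} 10.  `passes` is the conjunction of the four flags.
#'
#' @param desc A descriptor `data.frame` from [compute_descriptors()], or any
#'   data.frame/list with numeric `mw`, `logp`, `hbd`, `hba` entries.
#' @return A `data.frame` with logical columns `mw_ok`, `logp_ok`, `hbd_ok`,
#'   `hba_ok`, `passes`.
#' @export
check_ro5 <- function(desc) {
  desc <- as.data.frame(desc)
  needed <- c("mw", "logp", "hbd", "hba")
  if (!all(needed %in% names(desc))) {
    stop("descriptors must contain columns: ", paste(needed, collapse = ", "))
  }
  out <- data.frame(mw_ok = desc$mw <= 500,
                    logp_ok = desc$logp <= 5,
                    hbd_ok = desc$hbd <= 5,
                    hba_ok = desc$hba <= 10)
  out$passes <- out$mw_ok & out$logp_ok & out$hbd_ok & out$hba_ok
  out
}

#' Quantitative Estimate of Drug-likeness (QED)
#'
#' The weighted geometric mean of eight desirability-transformed descriptors
#' (Bickerton et al.), in \[0, 1\]; computed by RDKit's reference
#' implementation.
#'
#' @param text Character vector of valid SMILES.
#' @return Numeric vector of QED scores.
#' @export
compute_qed <- function(text) {
  props <- chem_props(text)
  if (any(!props$valid)) {
    bad <- text[!props$valid]
    stop("cannot compute QED for invalid SMILES: ",
         paste(dQuote(utils::head(bad, 5L)), collapse = ", "))
  }
  props$qed
}

# .smi I/O ---------------------------------------------------------------------

#' Read a .smi file
#'
#' One SMILES per line, with an optional tab-separated name; `#` comment
#' lines and blank lines are ignored.
#'
#' @param path File path.
#' @return A `data.frame` with columns `smiles` and `name` (NA when absent).
#' @export
read_smi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines, which = "right")
  lines <- lines[nchar(lines) > 0L & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(smiles = vapply(parts, `[`, character(1), 1L),
             name = vapply(parts, function(p) {
               if (length(p) >= 2L) p[[2L]] else NA_character_
             }, character(1)),
             stringsAsFactors = FALSE)
}

#' Write a .smi file
#'
#' @param smiles Character vector of SMILES.
#' @param path Output path.
#' @param names Optional names written tab-separated after each SMILES.
#' @return Invisibly, `path`.
#' @export
write_smi <- function(smiles, path, names = NULL) {
  lines <- if (is.null(names)) smiles else paste(smiles, names, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
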