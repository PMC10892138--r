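# Persistent RDKit worker -----------------------------------------------------
#
# All chemistry (SMILES parsing, canonicalization, descriptors, QED) is
# delegated to RDKit, the reference cheminformatics toolkit.  Because RDKit
# has no native R binding, the package keeps one long-running Python worker
# per session and talks to it over a pair of named pipes with a JSON-lines
# protocol.  Round trips cost on the order of a millisecond, and results are
# memoised per SMILES string, so the worker is cheap enough to sit inside a
# tree-search reward loop.

.chem <- new.env(parent = emptyenv())

#' Start the RDKit chemistry backend
#'
#' Launches the Python worker process that serves all chemistry queries.
#' Called automatically on first use; call it yourself only to fail fast
#' (e.g. at the top of a script) or after [chem_backend_stop()].
#'
#' @param python Path to the Python interpreter with RDKit available.
#'   Defaults to `getOption("mctsmol.python", "python")`.
#' @return Invisibly `TRUE` on success.
#' @export
chem_backend_start <- function(python = getOption("mctsmol.python", "python")) {
  if (isTRUE(.chem$alive)) {
    return(invisible(TRUE))
  }
  script <- system.file("python", "rdkit_worker.py", package = "mctsmol")
  if (script == "") {
    stop("rdkit_worker.py not found; is the package installed correctly?")
  }
  if (Sys.which(python) == "" && !file.exists(python)) {
    stop("Python interpreter not found: '", python,
         "'. Set options(mctsmol.python = ...) to the interpreter that has ",
         "RDKit installed.")
  }
  # Fail fast (and avoid a blocking fifo open) if RDKit is not importable.
  ok <- suppressWarnings(system2(python, c("-c", shQuote("import rdkit")),
                                 stdout = FALSE, stderr = FALSE))
  if (!identical(ok, 0L)) {
    stop("'", python, "' cannot import rdkit; the chemistry backend needs ",
         "a Python with RDKit installed (see option mctsmol.python).")
  }

  dir <- tempfile("mctsmol-chem-")
  dir.create(dir)
  fifo_in <- file.path(dir, "req")   # R writes, worker reads
  fifo_out <- file.path(dir, "resp") # worker writes, R reads
  status <- system2("mkfifo", shQuote(c(fifo_in, fifo_out)))
  if (!identical(status, 0L)) {
    stop("could not create named pipes for the chemistry backend")
  }
  log_file <- file.path(dir, "worker.log")
  system2(python, c("-u", shQuote(script), shQuote(fifo_in), shQuote(fifo_out)),
          wait = FALSE, stdout = log_file, stderr = log_file)

  # The worker opens request-read then response-write; mirror in order.
  .chem$con_in <- fifo(fifo_in, open = "w", blocking = TRUE)
  .chem$con_out <- fifo(fifo_out, open = "r", blocking = TRUE)
  .chem$dir <- dir
  .chem$log_file <- log_file
  .chem$next_id <- 1L
  .chem$cache <- new.env(parent = emptyenv())
  .chem$alive <- TRUE

  resp <- chem_request(list(op = "ping"))
  if (!isTRUE(resp$pong)) {
    chem_backend_stop()
    stop("chemistry backend failed its startup ping")
  }
  invisible(TRUE)
}

#' Stop the RDKit chemistry backend
#'
#' Closes the pipes; the worker process exits when it sees end-of-input.
#' @return Invisibly `TRUE`.
#' @export
chem_backend_stop <- function() {
  for (con in c("con_in", "con_out")) {
    if (!is.null(.chem[[con]])) {
      try(close(.chem[[con]]), silent = TRUE)
      .chem[[con]] <- NULL
    }
  }
  .chem$alive <- FALSE
  invisible(TRUE)
}

# One JSON-lines round trip with the worker.
chem_request <- function(body) {
  if (!isTRUE(.chem$alive)) {
    chem_backend_start()
  }
  id <- .chem$next_id
  .chem$next_id <- id + 1L
  body$id <- id
  writeLines(jsonlite::toJSON(body, auto_unbox = TRUE, null = "null"),
             .chem$con_in)
  flush(.chem$con_in)
  line <- readLines(.chem$con_out, n = 1L)
  if (length(line) == 0L) {
    .chem$alive <- FALSE
    diag <- if (!is.null(.chem$log_file) && file.exists(.chem$log_file)) {
      paste(readLines(.chem$log_file, warn = FALSE), collapse = "\n")
    } else ""
    stop("chemistry backend terminated unexpectedly.\n", diag)
  }
  resp <- jsonlite::fromJSON(line, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(resp$id, id)) {
    stop("chemistry backend protocol error: response id mismatch")
  }
  if (!isTRUE(resp$ok)) {
    stop("chemistry backend error: ", resp$error)
  }
  resp
}

# Properties for a character vector of SMILES, memoised.  Returns a
# data.frame aligned with `smiles`: valid, canonical, qed, mw, logp, hbd,
# hba, rotatable_bonds, rings.
chem_props <- function(smiles) {
  stopifnot(is.character(smiles))
  if (!isTRUE(.chem$alive)) {
    chem_backend_start()
  }
  invalid_row <- list(valid = FALSE, canonical = NA_character_,
                      qed = NA_real_, mw = NA_real_, logp = NA_real_,
                      hbd = NA_integer_, hba = NA_integer_,
                      rotatable_bonds = NA_integer_, rings = NA_integer_)
  # Cache keys: environments cannot hold "", so give it a sentinel key.
  keys <- ifelse(nchar(smiles) == 0L, ".__empty__", smiles)
  todo <- unique(smiles[!vapply(keys, exists, logical(1),
                                envir = .chem$cache, inherits = FALSE)])
  if (length(todo) > 0L) {
    resp <- chem_request(list(op = "props", smiles = I(todo)))
    for (res in resp$results) {
      row <- invalid_row
      if (isTRUE(res$valid)) {
        row <- list(valid = TRUE, canonical = res$canonical,
                    qed = as.numeric(res$qed), mw = as.numeric(res$mw),
                    logp = as.numeric(res$logp), hbd = as.integer(res$hbd),
                    hba = as.integer(res$hba),
                    rotatable_bonds = as.integer(res$rotatable_bonds),
                    rings = as.integer(res$rings))
      }
      key <- if (nchar(res$smiles) == 0L) ".__empty__" else res$smiles
      assign(key, row, envir = .chem$cache)
    }
  }
  rows <- lapply(keys, get, envir = .chem$cache, inherits = FALSE)
  out <- do.call(rbind, lapply(rows, as.data.frame,
                               stringsAsFactors = FALSE))
  out$smiles <- smiles
  rownames(out) <- NULL
  out[, c("smiles", "valid", "canonical", "qed", "mw", "logp", "hbd", "hba",
          "rotatable_bonds", "rings")]
}

# A non-canonical rewriting of a valid SMILES (random atom renumbering);
# used to probe canonicalization invariance.
chem_randomize_smiles <- function(smiles, seed) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  resp <- chem_request(list(op = "randomize", smiles = smiles,
                            seed = as.integer(seed)))
  resp$smiles
}

.onUnload <- function(libpath) {
  chem_backend_stop()
}
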