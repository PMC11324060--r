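# Thin wrapper around the Open Babel command-line tool (obabel), which
# provides canonical SMILES, charge neutralization and InChIKey generation.
# All calls are batched over temporary files; molecule titles carry the input
# index so that parse failures never misalign the output.

ob_available <- function() nzchar(Sys.which("obabel"))

.ob_require <- function() {
  if (!ob_available()) {
    stop("Open Babel (obabel) was not found on the PATH; it is required for ",
         "structure standardization.", call. = FALSE)
  }
}

.ob_run <- function(args, input_file) {
  out <- suppressWarnings(system2("obabel", shQuote(c(input_file, args)),
                                  stdout = TRUE, stderr = FALSE))
  status <- attr(out, "status")
  if (!is.null(status) && status > 1L) {
    stop("obabel failed (exit ", status, ")", call. = FALSE)
  }
  out
}

#' Canonical SMILES via Open Babel
#'
#' Converts SMILES strings to Open Babel's canonical form, optionally
#' removing all stereochemistry (racemization) and neutralizing +1/-1
#' charges. Entries that Open Babel cannot parse are returned as `NA`.
#'
#' @param smiles Character vector of SMILES strings.
#' @param strip_stereo Drop tetrahedral and double-bond stereo descriptors.
#' @param neutralize Neutralize +1/-1 charged atoms where chemically valid.
#' @return Character vector of canonical SMILES, `NA` where parsing failed.
#' @export
ob_canonical_smiles <- function(smiles, strip_stereo = TRUE, neutralize = FALSE) {
  .ob_require()
  n <- length(smiles)
  if (n == 0L) return(character(0))
  infile <- tempfile(fileext = ".smi")
  on.exit(unlink(infile), add = TRUE)
  writeLines(paste(smiles, paste0("fgidx", seq_len(n))), infile)
  args <- c("-ocan", "-e")
  if (strip_stereo) args <- c(args, "-xi")
  if (neutralize) args <- c(args, "--neutralize")
  out <- .ob_run(args, infile)
  res <- rep(NA_character_, n)
  if (length(out) > 0L) {
    parts <- strsplit(out, "\t", fixed = TRUE)
    for (p in parts) {
      if (length(p) >= 2L && grepl("^fgidx[0-9]+$", trimws(p[2]))) {
        idx <- as.integer(sub("fgidx", "", trimws(p[2])))
        res[idx] <- trimws(p[1])
      }
    }
  }
  res[!is.na(res) & res == ""] <- NA_character_
  res
}

#' SMARTS substructure screening via Open Babel
#'
#' @param smiles Character vector of SMILES strings.
#' @param smarts A single SMARTS pattern.
#' @return Logical vector: `TRUE` where the pattern matches (`NA` inputs
#'   never match).
#' @export
ob_smarts_match <- function(smiles, smarts) {
  .ob_require()
  n <- length(smiles)
  res <- rep(FALSE, n)
  ok <- !is.na(smiles) & nzchar(smiles)
  if (!any(ok)) return(res)
  infile <- tempfile(fileext = ".smi")
  on.exit(unlink(infile), add = TRUE)
  writeLines(paste(smiles[ok], paste0("fgidx", which(ok))), infile)
  out <- .ob_run(c("-osmi", "-e", paste0("-s", smarts)), infile)
  hits <- regmatches(out, regexpr("fgidx[0-9]+", out))
  idx <- as.integer(sub("fgidx", "", hits))
  res[idx[!is.na(idx)]] <- TRUE
  res
}

#' InChIKeys via Open Babel
#'
#' Computes standard InChIKeys. With the racemic canonical SMILES produced by
#' [ob_canonical_smiles()] (stereo stripped), the resulting keys are racemic
#' InChIKeys: all stereoisomers of a compound collapse onto one key, which is
#' the identity used for deduplication throughout the pipeline.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of 27-character InChIKeys, `NA` on failure.
#' @export
ob_inchikey <- function(smiles) {
  .ob_require()
  n <- length(smiles)
  if (n == 0L) return(character(0))
  res <- rep(NA_character_, n)
  ok <- !is.na(smiles) & nzchar(smiles)
  if (!any(ok)) return(res)
  infile <- tempfile(fileext = ".smi")
  on.exit(unlink(infile), add = TRUE)
  writeLines(smiles[ok], infile)
  out <- .ob_run(c("-oinchikey", "-e"), infile)
  out <- trimws(out[grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", trimws(out))])
  if (length(out) == sum(ok)) {
    res[ok] <- out
  } else {
    # a conversion failed somewhere: fall back to per-molecule calls
    idxs <- which(ok)
    for (i in idxs) {
      o <- .ob_run(c("-oinchikey", "-e"),
                   { f <- tempfile(fileext = ".smi"); writeLines(smiles[i], f); f })
      o <- trimws(o[grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", trimws(o))])
      if (length(o) == 1L) res[i] <- o
    }
  }
  res
}
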