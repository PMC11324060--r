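# PNP / NPL / NP / NonPNP status assignment against a natural-product
# reference. The reference holds two sets built from the NP library after
# the identical standardization and fragment analysis: the racemic
# InChIKeys of all NPs (structural identity) and the fragment-combination
# signatures observed in NPs.
#
# Precedence: identity to an NP wins over everything; a single fragment
# combination unseen in NPs makes a compound a PNP even when it also
# carries known combinations; compounds whose combinations are all known
# are NPL; everything else (no combinations, failed filters or processing)
# is NonPNP.

#' Build the natural-product reference
#'
#' @param np_records Standardized, filtered, deduplicated molecule table of
#'   the NP library.
#' @param catalog Fragment catalog.
#' @param config An [fg_config()]; `fcg_compare_level` decides whether the
#'   signature set stores whole-FCG signatures (`"graph"`) or individual
#'   edge strings (`"edge"`, default).
#' @param fcg_table Optional precomputed [classify_library()] output for
#'   `np_records`; computed when missing.
#' @return A list of class `fg_np_reference` with sorted character sets
#'   `np_inchikeys` and `np_signatures`, and the `fcg_compare_level` used.
#' @export
build_np_reference <- function(np_records, catalog, config = fg_config(),
                               fcg_table = NULL) {
  if (nrow(np_records) == 0L) stop("empty NP library")
  if (is.null(fcg_table)) fcg_table <- classify_library(np_records, catalog, config)
  sigs <- .fg_signature_units(fcg_table$signature, config$fcg_compare_level)
  structure(list(
    np_inchikeys = sort(unique(np_records$inchikey[!is.na(np_records$inchikey)])),
    np_signatures = sort(unique(sigs)),
    fcg_compare_level = config$fcg_compare_level
  ), class = "fg_np_reference")
}

# decompose FCG signatures into comparison units for the configured level
.fg_signature_units <- function(signatures, level) {
  if (length(signatures) == 0L) return(character(0))
  if (level == "graph") return(signatures)
  unlist(strsplit(signatures, "|", fixed = TRUE), use.names = FALSE)
}

#' Classify one molecule against the NP reference
#'
#' @param inchikey Racemic InChIKey of the molecule.
#' @param signatures Character vector of the molecule's FCG signatures
#'   (empty when it has none).
#' @param reference An `fg_np_reference`.
#' @return One of `"NP"`, `"PNP"`, `"NPL"`, `"NonPNP"`.
#' @export
classify_molecule <- function(inchikey, signatures, reference) {
  if (!is.na(inchikey) && inchikey %in% reference$np_inchikeys) return("NP")
  if (length(signatures) == 0L) return("NonPNP")
  units <- .fg_signature_units(signatures, reference$fcg_compare_level)
  if (any(!(units %in% reference$np_signatures))) return("PNP")
  "NPL"
}

#' Assign PNP status to a standardized library
#'
#' Fills the `status` column of a molecule table from its fragment analysis
#' and an NP reference. Records that failed standardization, filters, the
#' per-molecule timeout, or that have no fragment-combination graphs are
#' NonPNP (with `failure_reason` retained where applicable).
#'
#' @param records Standardized molecule table.
#' @param fcg_table Output of [classify_library()] for `records`.
#' @param reference An `fg_np_reference` from [build_np_reference()].
#' @return `records` with `status` (and `failure_reason` for timeouts)
#'   filled; every row carries exactly one of the four status values.
#' @export
assign_status <- function(records, fcg_table, reference) {
  failures <- attr(fcg_table, "failures")
  for (i in seq_len(nrow(records))) {
    sid <- records$source_id[i]
    if (!is.null(failures) && sid %in% names(failures)) {
      records$status[i] <- "NonPNP"
      records$failure_reason[i] <- failures[[sid]]
      next
    }
    if (!(records$passed_filters[i] %in% TRUE)) {
      records$status[i] <- "NonPNP"
      next
    }
    sigs <- fcg_table$signature[fcg_table$source_id == sid]
    records$status[i] <- classify_molecule(records$inchikey[i], sigs, reference)
  }
  records
}

#' Read / write an NP reference as JSON
#'
#' @param reference An `fg_np_reference`.
#' @param path JSON file path.
#' @return `read_np_reference()` returns the reference object.
#' @export
write_np_reference <- function(reference, path) {
  jsonlite::write_json(list(np_inchikeys = reference$np_inchikeys,
                            np_signatures = reference$np_signatures,
                            fcg_compare_level = reference$fcg_compare_level),
                       path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_np_reference
#' @export
read_np_reference <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(np_inchikeys = sort(unique(as.character(x$np_inchikeys))),
                 np_signatures = sort(unique(as.character(x$np_signatures))),
                 fcg_compare_level = as.character(x$fcg_compare_level)[1]),
            class = "fg_np_reference")
}
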