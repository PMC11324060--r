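# End-to-end pipeline: standardize -> catalog -> classify -> NP reference ->
# status -> merge-back, with a reproducibility manifest.

.fg_stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full fragment-combination pipeline
#'
#' Stages: read inputs, build the fragment catalog, standardize the analyte
#' and NP libraries, fragment-classify both, build the NP reference, assign
#' statuses, and merge statuses back onto the full (pre-deduplication)
#' library by InChIKey. All outputs are written to `out_dir` together with
#' a manifest (config snapshot, input digests, per-stage counts); re-running
#' with an identical manifest reproduces identical outputs.
#'
#' @param config A list or path to a YAML file with keys: `library`
#'   (SMILES-TSV path), `np_library` (SMILES-TSV path), `fragments`
#'   (SMILES-TSV of the fragment set), `out_dir`, and optionally `format`,
#'   `chunk_size`, `timeout_s`, `random_seed`, `connection_cutoff`,
#'   `fcg_compare_level`, `deglycosylate`, `neutralize`.
#' @return Invisibly, a list with the output tables and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (key in c("library", "np_library", "fragments", "out_dir")) {
    if (is.null(config[[key]])) stop("pipeline config is missing '", key, "'")
  }
  cfg <- fg_config(
    chunk_size = config$chunk_size %||% 100L,
    timeout_s = config$timeout_s %||% 50,
    random_seed = config$random_seed %||% 1L,
    connection_cutoff = config$connection_cutoff %||% 3L,
    fcg_compare_level = config$fcg_compare_level %||% "edge",
    deglycosylate = config$deglycosylate %||% TRUE,
    neutralize = config$neutralize %||% TRUE)
  fmt <- config$format %||% "smiles-tsv"
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  lib_full <- read_molecule_table(config$library, fmt)
  np_full <- read_molecule_table(config$np_library, fmt)
  frag_tab <- utils::read.delim(config$fragments, stringsAsFactors = FALSE)
  if (!"smiles" %in% names(frag_tab)) stop("fragment file needs a 'smiles' column")
  .fg_stage_log("read", nrow(lib_full), " library / ", nrow(np_full),
                " NP / ", nrow(frag_tab), " fragment records")

  catalog <- build_catalog(frag_tab$smiles)
  .fg_stage_log("catalog", nrow(catalog), " fragments")

  lib_std_full <- standardize_library(lib_full, cfg, dedup = FALSE)
  lib_std <- deduplicate(lib_std_full)
  np_std <- standardize_library(np_full, cfg, dedup = TRUE)
  .fg_stage_log("standardize", nrow(lib_std), " unique library / ",
                nrow(np_std), " unique NP molecules (",
                attr(lib_std, "n_duplicates"), " duplicates)")

  np_fcg <- classify_library(np_std, catalog, cfg)
  reference <- build_np_reference(np_std, catalog, cfg, fcg_table = np_fcg)
  lib_fcg <- classify_library(lib_std, catalog, cfg)
  .fg_stage_log("classify", nrow(lib_fcg), " FCG rows; reference holds ",
                length(reference$np_signatures), " signatures")

  lib_status <- assign_status(lib_std, lib_fcg, reference)
  # merge status back onto the full (pre-dedup) table by InChIKey
  key2status <- lib_status$status
  names(key2status) <- lib_status$inchikey
  merged <- lib_std_full
  has_key <- !is.na(merged$inchikey) & merged$inchikey %in% names(key2status)
  merged$status[has_key] <- key2status[merged$inchikey[has_key]]
  merged$status[is.na(merged$status)] <- "NonPNP"
  counts <- table(factor(lib_status$status,
                         levels = c("PNP", "NPL", "NP", "NonPNP")))
  .fg_stage_log("status", paste(names(counts), counts, sep = "=", collapse = " "))

  summary <- summarize_library(lib_status, lib_fcg)

  paths <- list(
    catalog = file.path(config$out_dir, "catalog.tsv"),
    status = file.path(config$out_dir, "status.tsv"),
    status_full = file.path(config$out_dir, "status_full.tsv"),
    fcg = file.path(config$out_dir, "fcg.tsv"),
    np_ref = file.path(config$out_dir, "np_ref.json"),
    summary = file.path(config$out_dir, "summary.json"),
    manifest = file.path(config$out_dir, "manifest.json"))
  write_catalog(catalog, paths$catalog)
  write_molecule_table(lib_status, paths$status)
  write_molecule_table(merged, paths$status_full)
  utils::write.table(lib_fcg, paths$fcg, sep = "\t", quote = FALSE, row.names = FALSE)
  write_np_reference(reference, paths$np_ref)
  jsonlite::write_json(list(
    status_counts = as.list(counts),
    ctype_percent = as.list(round(summary$ctype_percent, 4)),
    ctype_ratio = as.list(round(summary$ctype_ratio, 4))),
    paths$summary, auto_unbox = TRUE)

  manifest <- list(
    tool = "fraggraph",
    version = tryCatch(as.character(utils::packageVersion("fraggraph")),
                       error = function(e) "dev"),
    config = config[setdiff(names(config), "out_dir")],
    effective_config = unclass(cfg),
    input_digests = stats::setNames(
      as.list(unname(tools::md5sum(c(config$library, config$np_library,
                                     config$fragments)))),
      c("library", "np_library", "fragments")),
    catalog_digest = unname(tools::md5sum(paths$catalog)),
    counts = list(library_read = nrow(lib_full),
                  library_unique = nrow(lib_std),
                  duplicates = attr(lib_std, "n_duplicates"),
                  np_unique = nrow(np_std),
                  fcg_rows = nrow(lib_fcg),
                  status = as.list(counts)))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(status = lib_status, status_full = merged, fcg = lib_fcg,
                 catalog = catalog, reference = reference, summary = summary,
                 manifest = manifest, paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
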