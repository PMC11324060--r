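# Morphological (cell painting) profile analysis: induction, activity
# flagging, cluster-subprofile assignment and 2-D embedding.
#
# Profiles are modified-Z-scored feature vectors versus solvent controls
# (579 features in the standard assay). Induction is the percentage of
# significantly changed features; compounds at or above 5% induction count
# as active. Actives are assigned to reference bioactivity clusters by
# Pearson correlation on cluster-specific feature subsets ("subprofiles"),
# with an 80% similarity threshold.

.FG_N_FEATURES <- 579L

#' Read / write morphological profiles
#'
#' Profile tables are TSV with columns `id`, `concentration` and one column
#' per feature (feature order is preserved from the header).
#'
#' @param path TSV file.
#' @return A list with `meta` (data.frame: id, concentration), `mat`
#'   (numeric matrix, profiles in rows) and `features` (column names).
#' @export
read_profiles <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(all(c("id", "concentration") %in% names(tab)))
  feat <- setdiff(names(tab), c("id", "concentration"))
  mat <- as.matrix(tab[, feat, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- tab$id
  list(meta = data.frame(id = tab$id, concentration = tab$concentration,
                         stringsAsFactors = FALSE),
       mat = mat, features = feat)
}

#' @rdname read_profiles
#' @param profiles A list as returned by `read_profiles()`.
#' @export
write_profiles <- function(profiles, path) {
  tab <- cbind(profiles$meta, as.data.frame(profiles$mat))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Induction of a morphological profile
#'
#' The percentage of profile features whose absolute (modified Z-scored)
#' value reaches the significance threshold, relative to the full profile
#' length.
#'
#' @param features Numeric feature vector.
#' @param significance_threshold Absolute Z-score counting as significantly
#'   changed (default 3).
#' @param expected_length Required profile length (default 579; `NULL`
#'   skips the check).
#' @return Induction in percent (0-100).
#' @export
compute_induction <- function(features, significance_threshold = 3,
                              expected_length = .FG_N_FEATURES) {
  if (!is.null(expected_length) && length(features) != expected_length) {
    stop("profile has ", length(features), " features, expected ",
         expected_length)
  }
  100 * sum(abs(features) >= significance_threshold) / length(features)
}

#' Activity flag from induction
#'
#' @param induction Induction percentage(s).
#' @param min_induction Activity threshold in percent (default 5; compounds
#'   at exactly the threshold are active).
#' @return Logical vector.
#' @export
flag_active <- function(induction, min_induction = 5) {
  induction >= min_induction
}

#' Read / write cluster subprofiles
#'
#' Subprofile files are JSON arrays of objects with `cluster_name`,
#' `feature_subset` (1-based indices into the full profile) and `values`
#' (median reference vector on the subset).
#'
#' @param path JSON file.
#' @return A list of subprofiles.
#' @export
read_subprofiles <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(x)), function(i) {
    list(cluster_name = x$cluster_name[i],
         feature_subset = as.integer(x$feature_subset[[i]]),
         values = as.numeric(x$values[[i]]))
  })
}

#' @rdname read_subprofiles
#' @param subprofiles A list of subprofiles.
#' @export
write_subprofiles <- function(subprofiles, path) {
  jsonlite::write_json(
    data.frame(cluster_name = vapply(subprofiles, `[[`, character(1), "cluster_name"),
               feature_subset = I(lapply(subprofiles, `[[`, "feature_subset")),
               values = I(lapply(subprofiles, `[[`, "values"))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Assign an active profile to a bioactivity cluster
#'
#' Similarity to a cluster is 100 times the Pearson correlation between the
#' profile restricted to the cluster's feature subset and the cluster's
#' reference values. The best cluster is assigned when its similarity
#' reaches `min_similarity`; ties break by cluster name. A constant
#' restricted vector has undefined correlation and is treated as below
#' threshold.
#'
#' @param features Full-length profile vector.
#' @param subprofiles List of subprofiles (see [read_subprofiles()]).
#' @param min_similarity Assignment threshold in percent (default 80).
#' @return A list with `cluster` (name or `NA` when unassigned) and
#'   `similarity` (named vector of all cluster similarities).
#' @export
assign_cluster <- function(features, subprofiles, min_similarity = 80) {
  sims <- vapply(subprofiles, function(sp) {
    v <- features[sp$feature_subset]
    if (stats::sd(v) == 0 || stats::sd(sp$values) == 0) return(NA_real_)
    100 * stats::cor(v, sp$values)
  }, numeric(1))
  names(sims) <- vapply(subprofiles, `[[`, character(1), "cluster_name")
  usable <- !is.na(sims) & sims >= min_similarity
  if (!any(usable)) {
    return(list(cluster = NA_character_, similarity = sims))
  }
  best <- names(sims)[usable][order(-sims[usable], names(sims)[usable])][1]
  list(cluster = best, similarity = sims)
}

#' Analyze a set of morphological profiles
#'
#' Computes induction and activity for every profile and assigns actives to
#' clusters; inactive profiles are not assigned.
#'
#' @param profiles List from [read_profiles()] (or the same structure).
#' @param subprofiles List of cluster subprofiles.
#' @param significance_threshold Threshold for [compute_induction()].
#' @param min_induction Activity threshold in percent.
#' @param min_similarity Cluster assignment threshold in percent.
#' @return A data.frame: `id`, `concentration`, `induction`, `active`,
#'   `cluster` (NA = unassigned or inactive), `best_similarity`.
#' @export
analyze_profiles <- function(profiles, subprofiles,
                             significance_threshold = 3, min_induction = 5,
                             min_similarity = 80) {
  n <- nrow(profiles$mat)
  induction <- vapply(seq_len(n), function(i)
    compute_induction(profiles$mat[i, ], significance_threshold,
                      expected_length = ncol(profiles$mat)), numeric(1))
  active <- flag_active(induction, min_induction)
  cluster <- rep(NA_character_, n)
  best_sim <- rep(NA_real_, n)
  for (i in which(active)) {
    a <- assign_cluster(profiles$mat[i, ], subprofiles, min_similarity)
    cluster[i] <- a$cluster
    if (any(!is.na(a$similarity))) best_sim[i] <- max(a$similarity, na.rm = TRUE)
  }
  data.frame(id = profiles$meta$id, concentration = profiles$meta$concentration,
             induction = induction, active = active, cluster = cluster,
             best_similarity = best_sim, stringsAsFactors = FALSE)
}

#' Embed profiles in two dimensions
#'
#' Joint UMAP embedding of query profiles (typically the unassigned
#' actives) and optional reference/marker profiles on the full feature
#' vectors. Deterministic for a fixed seed (single-threaded). Falls back to
#' a PCA embedding with a message when the uwot package is unavailable.
#'
#' @param mat Numeric matrix of profiles (rows = compounds).
#' @param markers Optional matrix of marker profiles embedded jointly.
#' @param seed Integer seed.
#' @param n_neighbors UMAP neighborhood size (capped at n - 1).
#' @return A data.frame `id`, `x`, `y`, `role` (`"query"`/`"marker"`).
#' @export
embed_profiles <- function(mat, markers = NULL, seed = 1L, n_neighbors = 15L) {
  all_mat <- rbind(mat, markers)
  if (nrow(all_mat) < 2L) stop("need at least 2 profiles to embed")
  role <- c(rep("query", nrow(mat)),
            if (!is.null(markers)) rep("marker", nrow(markers)))
  ids <- rownames(all_mat)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(all_mat)))
  nn <- max(2L, min(n_neighbors, nrow(all_mat) - 1L))
  coords <- if (requireNamespace("uwot", quietly = TRUE)) {
    .fg_with_seed(seed,
      uwot::umap(all_mat, n_neighbors = nn, n_threads = 1, n_sgd_threads = 0,
                 batch = FALSE))
  } else {
    message("uwot not available; using PCA for the 2-D embedding")
    stats::prcomp(all_mat, rank. = 2L)$x[, 1:2, drop = FALSE]
  }
  data.frame(id = ids, x = coords[, 1], y = coords[, 2], role = role,
             stringsAsFactors = FALSE)
}
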