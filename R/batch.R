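#' Read and validate an image manifest
#'
#' A manifest is a CSV pairing micrographs with embryo identity: required
#' columns `embryo_id`, `timepoint` (`"0hpi"` / `"72hpi"`) and `image`
#' (file path, resolved relative to the manifest's directory); any further
#' columns (temperature, treatment, replicate, ...) are carried through as
#' group labels. Validation -- every `embryo_id` present exactly twice,
#' once per timepoint -- happens before any image is read, so a malformed
#' manifest fails fast and names the offending embryo.
#'
#' @param path path to the manifest CSV.
#' @return The validated manifest data frame (image paths made absolute).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path))
    stop("manifest not found: ", path, call. = FALSE)
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  base <- dirname(normalizePath(path))
  rel <- !grepl("^(/|[A-Za-z]:)", man$image)
  man$image[rel] <- file.path(base, man$image[rel])
  validate_manifest(man)
}

#' @rdname read_manifest
#' @param manifest a manifest data frame (e.g. built in code rather than
#'   read from disk).
#' @export
validate_manifest <- function(manifest) {
  req <- c("embryo_id", "timepoint", "image")
  missing_cols <- setdiff(req, names(manifest))
  if (length(missing_cols))
    stop("manifest is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad_tp <- !manifest$timepoint %in% c("0hpi", "72hpi")
  if (any(bad_tp))
    stop("manifest has invalid timepoint(s): ",
         paste(unique(manifest$timepoint[bad_tp]), collapse = ", "),
         " (must be \"0hpi\" or \"72hpi\")", call. = FALSE)
  if (nrow(manifest) == 0L)
    stop("manifest is empty", call. = FALSE)
  tab <- table(factor(manifest$embryo_id),
               factor(manifest$timepoint, levels = c("0hpi", "72hpi")))
  bad <- rownames(tab)[!(tab[, "0hpi"] == 1L & tab[, "72hpi"] == 1L)]
  if (length(bad))
    stop("manifest pairing error: embryo(s) without exactly one 0hpi and one 72hpi row: ",
         paste(bad, collapse = ", "), call. = FALSE)
  manifest
}

#' Run the proliferation pipeline over a manifest
#'
#' Maps [proliferation_index()] over every embryo pair in a manifest. An
#' embryo whose images cannot be processed (unreadable file, blank 0 hpi
#' baseline, ...) is never silently dropped: it is listed in the discard
#' report with the reason, and the remaining embryos are processed. The
#' per-embryo log of selected thresholds and flags is part of the results
#' table; full sweep curves can be retained for audit plots.
#'
#' @param manifest a manifest data frame (see [read_manifest()]) or a path
#'   to a manifest CSV.
#' @param tolerance decay tolerance for [select_threshold()].
#' @param t_max sweep extent.
#' @param epsilon stability band for PI classification.
#' @param output_dir optional directory; when given, `results.csv` and
#'   `discarded.csv` are written there (plus `sweep_<id>_<tp>.csv` when
#'   `keep_sweeps`).
#' @param keep_sweeps retain the full per-image sweep curves.
#' @return A `batch_result`: list with `results` (one row per processed
#'   embryo, sorted by `embryo_id`), `discarded` (embryo_id + reason), and
#'   `sweeps` (named list, when requested).
#' @export
run_batch <- function(manifest, tolerance = 0.10, t_max = 50L,
                      epsilon = 1e-9, output_dir = NULL,
                      keep_sweeps = FALSE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  manifest <- validate_manifest(manifest)
  group_cols <- setdiff(names(manifest), c("embryo_id", "timepoint", "image"))
  ids <- sort(unique(manifest$embryo_id))

  rows <- list(); discards <- list(); sweeps <- list()
  for (id in ids) {
    sub <- manifest[manifest$embryo_id == id, ]
    row0 <- sub[sub$timepoint == "0hpi", ]
    row72 <- sub[sub$timepoint == "72hpi", ]
    res <- tryCatch({
      img0 <- load_gfp_image(row0$image)
      img72 <- load_gfp_image(row72$image)
      grp <- as.list(row0[group_cols])
      rec0 <- embryo_record(id, "0hpi", img0, grp)
      rec72 <- embryo_record(id, "72hpi", img72, grp)
      proliferation_index(rec0, rec72, tolerance = tolerance,
                          t_max = t_max, epsilon = epsilon)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      discards[[id]] <- data.frame(embryo_id = id,
                                   reason = conditionMessage(res),
                                   stringsAsFactors = FALSE)
      next
    }
    if (keep_sweeps) {
      sweeps[[paste0(id, "_0hpi")]] <-
        as.data.frame(compute_sweep(load_gfp_image(row0$image), t_max))
      sweeps[[paste0(id, "_72hpi")]] <-
        as.data.frame(compute_sweep(load_gfp_image(row72$image), t_max))
    }
    base <- data.frame(embryo_id = id, stringsAsFactors = FALSE)
    for (gc in group_cols) base[[gc]] <- row0[[gc]]
    base$shared_threshold <- res$shared_threshold
    base$ngfp_0 <- res$m0$ngfp; base$gmv_0 <- res$m0$gmv
    base$ngfp_72 <- res$m72$ngfp; base$gmv_72 <- res$m72$gmv
    base$pi <- res$pi
    base$classification <- res$classification
    base$flat_curve_0 <- res$selection_0$flat_curve
    base$saturated_0 <- res$selection_0$saturated
    base$flat_curve_72 <- if (is.null(res$selection_72)) NA else res$selection_72$flat_curve
    base$saturated_72 <- if (is.null(res$selection_72)) NA else res$selection_72$saturated
    rows[[id]] <- base
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    data.frame(embryo_id = character(0))
  discarded <- if (length(discards)) do.call(rbind, discards) else
    data.frame(embryo_id = character(0), reason = character(0))
  rownames(results) <- NULL; rownames(discarded) <- NULL
  out <- structure(list(results = results, discarded = discarded,
                        sweeps = if (keep_sweeps) sweeps else NULL),
                   class = "batch_result")
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(results, file.path(output_dir, "results.csv"),
                     row.names = FALSE)
    utils::write.csv(discarded, file.path(output_dir, "discarded.csv"),
                     row.names = FALSE)
    if (keep_sweeps)
      for (nm in names(sweeps))
        utils::write.csv(sweeps[[nm]],
                         file.path(output_dir, paste0("sweep_", nm, ".csv")),
                         row.names = FALSE)
  }
  out
}

#' @export
print.batch_result <- function(x, ...) {
  cat(sprintf("<batch_result> %d embryo(s) processed, %d discarded\n",
              nrow(x$results), nrow(x$discarded)))
  invisible(x)
}

#' Group-level analysis of per-embryo proliferation indices
#'
#' For each level of a grouping column: applies the IQR outlier filter to
#' the PI values (groups with fewer than 4 embryos are passed through
#' unfiltered and flagged), summarizes the kept values, and compares every
#' pair of groups with [compare_groups()].
#'
#' @param results a `batch_result` or its `results` data frame.
#' @param grouping name of the column whose levels define the groups (or a
#'   vector of column names, combined with "/").
#' @param alpha significance level for the pairwise comparisons.
#' @param k IQR fence multiplier.
#' @return A `group_analysis`: list with `summary` (per group: `n_raw`,
#'   `n_kept`, `n_outliers`, `filtered`, `mean_pi`, `sd_pi`) and
#'   `comparisons` (per pair: test path, statistic, p, significance stars).
#' @export
run_group_analysis <- function(results, grouping, alpha = 0.05, k = 1.5) {
  if (inherits(results, "batch_result")) results <- results$results
  if (!all(grouping %in% names(results)))
    stop("grouping column(s) not found in results: ",
         paste(setdiff(grouping, names(results)), collapse = ", "),
         call. = FALSE)
  key <- do.call(paste, c(results[grouping], sep = "/"))
  groups <- split(results$pi, key)
  if (length(groups) < 2L)
    stop("group analysis needs at least 2 groups (got ", length(groups), ")",
         call. = FALSE)

  kept <- list(); summ <- list()
  for (g in names(groups)) {
    v <- groups[[g]]
    if (length(v) >= 4L) {
      f <- iqr_filter(v, k)
      kept[[g]] <- f$kept
      filtered <- TRUE; n_out <- length(f$outliers)
    } else {
      kept[[g]] <- v
      filtered <- FALSE; n_out <- 0L
    }
    summ[[g]] <- data.frame(
      group = g, n_raw = length(v), n_kept = length(kept[[g]]),
      n_outliers = n_out, filtered = filtered,
      mean_pi = mean(kept[[g]]),
      sd_pi = if (length(kept[[g]]) > 1L) stats::sd(kept[[g]]) else NA_real_,
      stringsAsFactors = FALSE)
  }
  summary_df <- do.call(rbind, summ); rownames(summary_df) <- NULL

  pairs <- utils::combn(names(groups), 2L, simplify = FALSE)
  comps <- lapply(pairs, function(p) {
    cr <- compare_groups(kept[[p[1L]]], kept[[p[2L]]], alpha = alpha)
    data.frame(group_a = p[1L], group_b = p[2L],
               test_used = cr$test_used, homoscedastic = cr$homoscedastic,
               statistic = cr$statistic, p_value = cr$p_value,
               significant = cr$significant,
               stars = significance_stars(cr$p_value),
               stringsAsFactors = FALSE)
  })
  comparisons <- do.call(rbind, comps); rownames(comparisons) <- NULL
  structure(list(summary = summary_df, comparisons = comparisons,
                 alpha = alpha),
            class = "group_analysis")
}

#' @export
print.group_analysis <- function(x, ...) {
  cat("<group_analysis>\n")
  print(x$summary)
  cat("\npairwise comparisons (alpha =", x$alpha, "):\n")
  print(x$comparisons)
  invisible(x)
}
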