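#' MADRS change ratio
#'
#' The response metric: the ratio of a later MADRS score to the baseline score.
#' A ratio of 0.5 or less is a 50% reduction, i.e. treatment response.
#'
#' @param score_t0 Baseline MADRS (must be positive; inclusion guarantees
#'   values of at least 21).
#' @param score_later MADRS at the later visit.
#' @return `score_later / score_t0` (vectorised).
#' @export
#' @examples
#' delta_madrs(30, 15)  # 0.5, exactly at the response boundary
delta_madrs <- function(score_t0, score_later) {
  if (any(score_t0 <= 0)) {
    stop("baseline MADRS must be positive to form the change ratio",
         call. = FALSE)
  }
  score_later / score_t0
}

#' Classify response trajectories from the 5-visit MADRS panel
#'
#' Applies the 50%-reduction rule: a subject is a responder iff their week-8
#' MADRS is at most half the week-0 value (boundary inclusive), an early
#' responder if the criterion is already met at week 2, and a later responder
#' otherwise.  Nonresponders are descriptively subtyped: "relapse" if the
#' minimum MADRS occurs before week 8 and the score then rises by more than
#' 20% of baseline, else "flat".  The subtype is merged (all "nonresponder")
#' for analysis, matching how the two nonresponse trajectories are pooled.
#'
#' @param madrs A tibble with `subject_id` and columns
#'   `madrs_w0`, `madrs_w2`, `madrs_w4`, `madrs_w6`, `madrs_w8` (complete
#'   cases only; rows with any missing visit are rejected).
#' @return A tibble: `subject_id`, `delta_madrs_t2`, `delta_madrs_t8`, `label`
#'   (early_responder / later_responder / nonresponder), `nr_subtype`
#'   (flat / relapse / not_applicable).
#' @export
#' @examples
#' classify_response(tibble::tibble(
#'   subject_id = c("a", "b", "c"),
#'   madrs_w0 = c(30, 30, 30), madrs_w2 = c(14, 20, 28),
#'   madrs_w4 = c(10, 16, 29), madrs_w6 = c(8, 14, 27),
#'   madrs_w8 = c(6, 12, 28)))
classify_response <- function(madrs) {
  cols <- paste0("madrs_w", madrs_weeks)
  missing <- setdiff(cols, names(madrs))
  if (length(missing)) {
    stop("missing MADRS columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(madrs[, cols])
  if (anyNA(m)) {
    stop("incomplete MADRS panel: complete cases at all 5 visits are required",
         call. = FALSE)
  }
  r2 <- delta_madrs(m[, 1L], m[, 2L])
  r8 <- delta_madrs(m[, 1L], m[, 5L])
  label <- dplyr::case_when(
    r8 <= 0.5 & r2 <= 0.5 ~ "early_responder",
    r8 <= 0.5 ~ "later_responder",
    TRUE ~ "nonresponder")

  nadir_week <- apply(m, 1L, which.min)  # first minimum; ties -> earliest
  rise <- m[, 5L] - m[cbind(seq_len(nrow(m)), nadir_week)]
  nr_subtype <- dplyr::case_when(
    label != "nonresponder" ~ "not_applicable",
    nadir_week < 5L & rise > 0.2 * m[, 1L] ~ "relapse",
    TRUE ~ "flat")
  tibble::tibble(subject_id = madrs$subject_id,
                 delta_madrs_t2 = r2, delta_madrs_t8 = r8,
                 label = label, nr_subtype = nr_subtype)
}

#' Calinski-Harabasz criterion
#'
#' The variance-ratio index used to choose the number of trajectory clusters:
#' `[B / (k - 1)] / [W / (n - k)]`, where B is the between-cluster sum of
#' squared distances of centroids to the grand mean weighted by cluster size
#' and W the within-cluster sum of squares.  A degenerate partition with
#' W = 0 returns `Inf`.
#'
#' @param x Numeric matrix (subjects x features).
#' @param labels Cluster assignment, one per row; at least 2 nonempty clusters.
#' @return The criterion value.
#' @export
calinski_harabasz <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.factor(labels)
  k <- nlevels(droplevels(labels))
  n <- nrow(x)
  if (k < 2L) stop("Calinski-Harabasz needs at least 2 nonempty clusters",
                   call. = FALSE)
  grand <- colMeans(x)
  B <- 0; W <- 0
  for (lv in levels(droplevels(labels))) {
    xi <- x[labels == lv, , drop = FALSE]
    ci <- colMeans(xi)
    B <- B + nrow(xi) * sum((ci - grand)^2)
    W <- W + sum(sweep(xi, 2L, ci)^2)
  }
  if (W == 0) return(Inf)
  (B / (k - 1)) / (W / (n - k))
}

#' Longitudinal k-means clustering of MADRS trajectories
#'
#' Runs Lloyd's k-means (Euclidean distance on the 5-visit trajectory vectors)
#' for each candidate k with `n_restarts` deterministic random initialisations,
#' keeps the restart with minimal within-cluster sum of squares, and selects
#' the k maximising the Calinski-Harabasz criterion.
#'
#' @param madrs A tibble as for [classify_response()], or a numeric matrix of
#'   trajectories.
#' @param k_candidates Integer vector of cluster counts to try (each < number
#'   of subjects).
#' @param n_restarts Random restarts per k (>= 1).
#' @param seed Integer seed for the restart stream (mandatory).
#' @return A list of class `kml_result`: `per_k` tibble (`k`,
#'   `calinski_harabasz`, `best_inertia`, `n_restarts`), `selected_k`,
#'   `assignments` tibble (`subject_id`, `cluster`) and `centroids` for the
#'   selected k, plus `fits` (the per-k assignment vectors and centroids).
#' @export
kml_cluster <- function(madrs, k_candidates = 2:6, n_restarts = 50L, seed) {
  if (missing(seed)) stop("`seed` is mandatory for kml_cluster", call. = FALSE)
  if (is.data.frame(madrs)) {
    ids <- madrs$subject_id
    x <- as.matrix(madrs[, paste0("madrs_w", madrs_weeks)])
  } else {
    x <- as.matrix(madrs)
    ids <- rownames(x)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  }
  n <- nrow(x)
  if (any(k_candidates >= n)) {
    stop("every candidate k must be smaller than the number of subjects",
         call. = FALSE)
  }
  stopifnot(n_restarts >= 1L)
  set.seed(seed)
  fits <- list()
  per_k <- purrr::map_dfr(sort(unique(as.integer(k_candidates))), function(k) {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      centers <- x[sample.int(n, k), , drop = FALSE]
      fit <- tryCatch(
        suppressWarnings(stats::kmeans(x, centers = centers, iter.max = 100L,
                                       algorithm = "Lloyd")),
        error = function(e) NULL)  # empty-cluster restart discarded
      if (is.null(fit) || length(unique(fit$cluster)) < k) next
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    if (is.null(best)) {
      warning("no k-means restart produced ", k,
              " nonempty clusters; skipping k = ", k, call. = FALSE)
      return(NULL)
    }
    ch <- calinski_harabasz(x, best$cluster)
    fits[[as.character(k)]] <<- list(assignments = best$cluster,
                                     centroids = best$centers)
    tibble::tibble(k = k, calinski_harabasz = ch,
                   best_inertia = best$tot.withinss,
                   n_restarts = as.integer(n_restarts))
  })
  if (nrow(per_k) == 0L) {
    stop("no candidate k produced a valid clustering", call. = FALSE)
  }
  sel <- per_k$k[which.max(per_k$calinski_harabasz)]
  best_fit <- fits[[as.character(sel)]]
  structure(list(per_k = per_k, selected_k = sel,
                 assignments = tibble::tibble(subject_id = ids,
                                              cluster = unname(best_fit$assignments)),
                 centroids = best_fit$centroids,
                 fits = fits),
            class = "kml_result")
}

#' @export
print.kml_result <- function(x, ...) {
  cat("Longitudinal k-means over k = {",
      paste(x$per_k$k, collapse = ", "), "}\n", sep = "")
  cat("Selected k =", x$selected_k, "by Calinski-Harabasz\n")
  print(x$per_k)
  invisible(x)
}
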