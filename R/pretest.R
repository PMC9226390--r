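#' Clean audiovisual-dominance pre-test records
#'
#' Removes practice trials (the first 12), incorrect responses and reaction
#' times above 1500 ms. Participants left without at least one valid trial
#' in every modality are excluded with a warning. Cleaning is idempotent.
#'
#' @param records data.frame with columns \code{participant}, \code{index},
#'   \code{modality} (Au/Vi/AV), \code{rt_ms}, \code{correct}; an optional
#'   \code{is_practice} column overrides the index rule.
#' @param rt_max reaction-time cutoff in ms (default 1500).
#' @return the cleaned data.frame.
#' @export
clean_pretest <- function(records, rt_max = 1500) {
  need <- c("participant", "index", "modality", "rt_ms", "correct")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  if (any(records$rt_ms <= 0)) stop("rt_ms must be positive")
  practice <- if ("is_practice" %in% names(records)) records$is_practice
              else records$index <= 12L
  keep <- !practice & records$correct & records$rt_ms <= rt_max
  out <- records[keep, , drop = FALSE]
  # flag participants missing a modality entirely after cleaning
  tab <- table(out$participant, out$modality)
  bad <- rownames(tab)[apply(tab[, c("Au", "Vi", "AV"), drop = FALSE] == 0L, 1, any)]
  if (length(bad)) {
    warning("excluding participant(s) with an empty modality after cleaning: ",
            paste(bad, collapse = ", "))
    out <- out[!(out$participant %in% bad), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Per-participant modality mean reaction times
#'
#' @param records cleaned pre-test records (see [clean_pretest()]).
#' @return data.frame with one row per participant: \code{participant},
#'   \code{mean_au}, \code{mean_vi}, \code{mean_av}, \code{n_valid}.
#' @export
rt_profiles <- function(records) {
  ag <- stats::aggregate(rt_ms ~ participant + modality, data = records, FUN = mean)
  wide <- stats::reshape(ag, idvar = "participant", timevar = "modality",
                         direction = "wide")
  names(wide) <- sub("^rt_ms\\.", "mean_", tolower(names(wide)))
  nv <- stats::aggregate(rt_ms ~ participant, data = records, FUN = length)
  wide$n_valid <- nv$rt_ms[match(wide$participant, nv$participant)]
  if (anyNA(wide)) stop("participant with missing modality mean; clean first")
  wide <- wide[order(wide$participant), c("participant", "mean_au", "mean_vi",
                                          "mean_av", "n_valid")]
  rownames(wide) <- NULL
  wide
}

#' Classify participants as auditory- or visually-dominant
#'
#' 2-means clustering (Lloyd's algorithm, Euclidean distance, best of
#' \code{n_restarts} by within-cluster sum of squares) on the raw
#' (mean Au, mean Vi, mean AV) reaction-time profiles. The cluster whose
#' centroid has the smaller Vi - Au contrast (relatively faster visual
#' responses) is labelled \code{VIS}, the other \code{AUD}.
#'
#' @param profiles data.frame from [rt_profiles()].
#' @param seed optional integer seed for the k-means restarts.
#' @param n_restarts number of random restarts (default 20).
#' @return data.frame \code{participant}, \code{label}, \code{mean_au},
#'   \code{mean_vi}, \code{mean_av}; the 2 x 3 centroid matrix is attached
#'   as attribute \code{"centroids"}.
#' @export
cluster_dominance <- function(profiles, seed = NULL, n_restarts = 20L) {
  m <- as.matrix(profiles[, c("mean_au", "mean_vi", "mean_av")])
  if (nrow(unique(m)) < 2L) stop("need at least 2 distinct RT profiles")
  km <- with_seed(seed, {
    res <- NULL
    for (attempt in 1:10) {   # Lloyd restarts can hit an empty cluster
      res <- tryCatch(
        stats::kmeans(m, centers = 2L, nstart = n_restarts,
                      algorithm = "Lloyd", iter.max = 100L),
        error = function(e) NULL)
      if (!is.null(res)) break
    }
    if (is.null(res)) stop("k-means failed: degenerate profile configuration")
    res
  })
  contrast <- km$centers[, "mean_vi"] - km$centers[, "mean_au"]
  lab <- ifelse(km$cluster == which.min(contrast), "VIS", "AUD")
  out <- data.frame(participant = profiles$participant, label = lab,
                    profiles[, c("mean_au", "mean_vi", "mean_av")],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "centroids") <- km$centers
  out
}
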