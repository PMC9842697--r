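#' Dynamic time warping distance
#'
#' Classic dynamic-programming DTW with the symmetric1 step pattern and
#' absolute-difference local cost, no window constraint. Optionally
#' z-normalises both series first (off by default). A display cap can
#' be recorded without altering the returned value.
#'
#' @param x,y numeric series, non-empty, no missing values.
#' @param cap optional display cap; when the distance exceeds it the
#'   result carries attribute `capped = TRUE`.
#' @param znorm z-normalise the inputs before alignment.
#' @return the DTW distance (>= 0).
#' @export
dtw_distance <- function(x, y, cap = NULL, znorm = FALSE) {
  if (!length(x) || !length(y)) stop("series must be non-empty")
  if (anyNA(x) || anyNA(y))
    stop("DTW requires gap-free series; impute first")
  if (znorm) {
    zn <- function(v) if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v - mean(v)
    x <- zn(x); y <- zn(y)
  }
  d <- .dtw_dp(as.numeric(x), as.numeric(y))
  if (!is.null(cap) && d > cap) attr(d, "capped") <- TRUE
  d
}

#' Pearson correlation with an explicit undefined marker
#'
#' Standard Pearson r; when either series has zero variance the
#' correlation is mathematically undefined and `NA` is returned (the
#' behaviour shown as empty cells in similarity matrices).
#'
#' @param x,y equal-length numeric series (length >= 2).
#' @return r in `[-1, 1]`, or `NA` when undefined.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("series lengths differ")
  if (length(x) < 2) stop("need at least two samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' DTW and Pearson similarity of a target channel to all channels
#'
#' For one run, computes the DTW distance and Pearson correlation of
#' the target (typically MRI) against every channel of the frame,
#' the per-run row of a multi-run similarity matrix. DTW distances
#' above the display cap are flagged in `dtw_capped`.
#'
#' @param frame a `tcf`.
#' @param target target channel name.
#' @param cap DTW display cap (default 6000).
#' @param znorm passed to [dtw_distance()].
#' @return list with `dtw`, `dtw_capped`, `pearson` (named one-row
#'   matrices keyed by channel).
#' @export
similarity_matrices <- function(frame, target = "MRI", cap = 6000,
                                znorm = FALSE) {
  y <- tcf_channel(frame, target)
  ok <- !is.na(y)
  chs <- names(frame$channels)
  dtw <- pearson <- matrix(NA_real_, 1, length(chs),
                           dimnames = list(target, chs))
  capped <- matrix(FALSE, 1, length(chs), dimnames = list(target, chs))
  for (ch in chs) {
    v <- frame$channels[[ch]]
    keep <- ok & !is.na(v)
    d <- dtw_distance(v[keep], y[keep], cap = cap, znorm = znorm)
    dtw[1, ch] <- as.numeric(d)
    capped[1, ch] <- isTRUE(attr(d, "capped"))
    pearson[1, ch] <- pearson_correlation(v[keep], y[keep])
  }
  list(dtw = dtw, dtw_capped = capped, pearson = pearson)
}

#' Rule-based feature selection for online bioprocess channels
#'
#' Drops, with an audit trail: (a) channels held constant across all
#' supplied runs (set points never moved), (b) channels without
#' significant temporal variation within runs, and (c) one member of
#' each channel pair whose absolute Pearson correlation reaches the
#' threshold - keeping the member more correlated with the target and
#' breaking ties by dropping the name that sorts later.
#'
#' @param frames a `tcf` or list of `tcf` runs.
#' @param target target channel name (excluded from pruning).
#' @param pearson_threshold collinearity threshold on `|r|`.
#' @param var_tol variance tolerance (after amplitude scaling) below
#'   which a channel counts as temporally constant.
#' @return list with `keep` (retained channel names) and `audit`
#'   (data.frame: channel, action, rule).
#' @export
select_features <- function(frames, target = "MRI",
                            pearson_threshold = 0.95, var_tol = 1e-12) {
  if (inherits(frames, "tcf")) frames <- list(frames)
  chs <- names(frames[[1]]$channels)
  chs <- setdiff(chs, target)
  audit <- data.frame(channel = character(0), action = character(0),
                      rule = character(0), stringsAsFactors = FALSE)
  drop <- function(ch, rule) {
    audit <<- rbind(audit, data.frame(channel = ch, action = "dropped",
                                      rule = rule))
  }
  scaled_var <- function(v) {
    v <- v[!is.na(v)]
    stats::var(v / max(1, abs(mean(v))))
  }
  keep <- character(0)
  for (ch in sort(chs)) {
    pooled <- unlist(lapply(frames, function(f) f$channels[[ch]]))
    pooled <- pooled[!is.na(pooled)]
    if (length(unique(pooled)) == 1L) {
      drop(ch, "constant across runs")
    } else if (all(vapply(frames, function(f)
      scaled_var(f$channels[[ch]]) < var_tol, TRUE))) {
      drop(ch, "no significant temporal variation")
    } else {
      keep <- c(keep, ch)
    }
  }
  ## collinearity pruning on pooled series, target correlation decides
  pool <- function(ch) unlist(lapply(frames, function(f) f$channels[[ch]]))
  tv <- pool(target)
  repeat {
    if (length(keep) < 2) break
    pr <- vapply(keep, function(a) vapply(keep, function(b) {
      ok <- stats::complete.cases(pool(a), pool(b))
      abs(pearson_correlation(pool(a)[ok], pool(b)[ok]))
    }, 0), numeric(length(keep)))
    diag(pr) <- 0
    if (all(is.na(pr)) || max(pr, na.rm = TRUE) < pearson_threshold) break
    ij <- which(pr == max(pr, na.rm = TRUE), arr.ind = TRUE)[1, ]
    a <- keep[ij[1]]; b <- keep[ij[2]]
    rt <- function(ch) {
      ok <- stats::complete.cases(pool(ch), tv)
      r <- pearson_correlation(pool(ch)[ok], tv[ok])
      if (is.na(r)) 0 else abs(r)
    }
    victim <- if (rt(a) > rt(b)) b
    else if (rt(a) < rt(b)) a
    else max(a, b)          # tie-break: drop the later-sorting name
    drop(victim, sprintf("collinear with %s (|r| >= %.2f)",
                         setdiff(c(a, b), victim), pearson_threshold))
    keep <- setdiff(keep, victim)
  }
  list(keep = keep, audit = audit)
}

#' Write similarity matrices and a selection audit to disk
#'
#' Matrices go to CSV with channel-name headers; the audit trail to
#' JSON.
#' @param sim result of [similarity_matrices()].
#' @param sel result of [select_features()].
#' @param dir output directory.
#' @export
write_feature_report <- function(sim, sel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(sim$dtw, file.path(dir, "dtw_matrix.csv"))
  utils::write.csv(sim$pearson, file.path(dir, "pearson_matrix.csv"))
  jsonlite::write_json(sel, file.path(dir, "feature_selection.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
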