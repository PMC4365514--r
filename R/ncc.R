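#' Normalized cross-correlation of two equally sized windows
#'
#' `ncc = sum((a - mean(a)) * (b - mean(b))) / (n * sd(a) * sd(b))` with
#' population standard deviations, so the score lies in `[-1, 1]` and is
#' invariant to affine intensity changes `a*x + b` (a > 0) of either
#' window.
#'
#' @param a,b Numeric matrices of identical dimension.
#' @return Correlation score in `[-1, 1]`; `NA` if either window has zero
#'   variance.
#' @export
ncc_score <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  a <- as.numeric(a); b <- as.numeric(b)
  da <- a - mean(a); db <- b - mean(b)
  va <- sum(da^2); vb <- sum(db^2)
  if (va <= 0 || vb <= 0) return(NA_real_)
  sum(da * db) / sqrt(va * vb)
}

extract_window <- function(mat, center, half) {
  r0 <- round(center[1]); c0 <- round(center[2])
  rs <- (r0 - half):(r0 + half); cs <- (c0 - half):(c0 + half)
  if (rs[1] < 1 || cs[1] < 1 || rs[length(rs)] > nrow(mat) ||
      cs[length(cs)] > ncol(mat))
    return(NULL)
  mat[rs, cs]
}

#' Refine a marker position by normalized cross-correlation
#'
#' Cuts a square template of half-size `window_px` around the marker in
#' the template image (the B+NIR sensor in the reference workflow) and
#' exhaustively correlates it against the search image over integer
#' offsets up to `slack_px` around the marker's nominal position there.
#' Ties in the maximal score are broken by the smallest offset magnitude,
#' then by row-major order of the offset.
#'
#' @param template_img,search_img [sensor_image()]s. Correlation runs on
#'   the `"B"` channel when present, else the first channel.
#' @param marker Marker observation (from [detect_markers()]): `center` is
#'   used both to cut the template and as the nominal search position.
#' @param search_center Optional `c(row, col)` nominal position in the
#'   search image when it differs from `marker$center`.
#' @param window_px Template half-size in pixels (template is
#'   `(2*window_px+1)^2`).
#' @param slack_px Maximum absolute offset searched in each direction.
#' @return The marker relocated in the search image: `center` is the
#'   NCC-maximizing position, `score` the maximal correlation.
#' @export
refine_by_ncc <- function(template_img, search_img, marker,
                          search_center = NULL, window_px = 10L,
                          slack_px = 8L) {
  stopifnot(inherits(template_img, "sensor_image"),
            inherits(search_img, "sensor_image"))
  chT <- if ("B" %in% template_img$channel_names) "B" else
    template_img$channel_names[1]
  chS <- if ("B" %in% search_img$channel_names) "B" else
    search_img$channel_names[1]
  tm <- get_channel(template_img, chT)
  sm <- get_channel(search_img, chS)
  tmpl <- extract_window(tm, marker$center, window_px)
  if (is.null(tmpl))
    stop("template window extends outside the template image", call. = FALSE)
  if (stats::sd(tmpl) == 0)
    stop("undefined correlation: zero-variance template", call. = FALSE)
  if (is.null(search_center)) search_center <- marker$center
  base <- round(search_center)
  offs <- expand.grid(dr = -slack_px:slack_px, dc = -slack_px:slack_px)
  best <- NULL
  for (i in seq_len(nrow(offs))) {
    ctr <- base + c(offs$dr[i], offs$dc[i])
    win <- extract_window(sm, ctr, window_px)
    if (is.null(win)) next
    s <- ncc_score(tmpl, win)
    if (is.na(s)) next
    cand <- list(score = s, dr = offs$dr[i], dc = offs$dc[i])
    if (is.null(best) || s > best$score + 1e-12 ||
        (abs(s - best$score) <= 1e-12 && better_tie(cand, best))) {
      best <- cand
    }
  }
  if (is.null(best))
    stop("undefined correlation: no searchable window with nonzero variance",
         call. = FALSE)
  out <- marker
  out$center <- base + c(best$dr, best$dc)
  out$score <- best$score
  out$source_channel <- chS
  out
}

# tie-break: smaller offset magnitude first, then row-major (dr, then dc)
better_tie <- function(a, b) {
  ma <- a$dr^2 + a$dc^2; mb <- b$dr^2 + b$dc^2
  if (ma != mb) return(ma < mb)
  if (a$dr != b$dr) return(a$dr < b$dr)
  a$dc < b$dc
}
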