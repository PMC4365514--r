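#' Detect circular field markers in a sensor image
#'
#' Finds the round fiducial plates (dark in the optical blue channel,
#' warmer than plants and soil in the thermal channel) by quantile
#' thresholding, connected-component labelling, and filters on blob area,
#' circularity (`4*pi*A/P^2`) and solidity. Centers are refined to
#' sub-pixel precision by the contrast-weighted centroid of each accepted
#' blob.
#'
#' @param img A [sensor_image()]. Detection uses the `"B"` channel when
#'   present (optical sensors), else the single channel (thermal).
#' @param polarity `"dark"` (optical markers) or `"bright"` (thermal).
#' @param expected_radius_px Numeric `c(min, max)` marker radius in pixels.
#' @param max_markers Maximum number of markers to return.
#' @param threshold_quantile Optional intensity quantile defining the blob
#'   threshold directly. By default the threshold is the midpoint between
#'   the extreme-quantile intensity (the marker level, located via the
#'   expected area of one smallest marker) and the image median (the
#'   background level), which stays clear of background noise tails.
#' @param min_circularity,min_solidity Shape filters.
#' @return A list of marker observations, each a list with `center`
#'   (c(row, col), sub-pixel), `radius` (px), `score` in `[0, 1]` and
#'   `source_channel`; sorted by score, then by blob contrast.
#'   Fewer than four detections raise a condition of class
#'   `aerophen_registration_infeasible` carrying the partial list in its
#'   `markers` field (the manual-override entry point).
#' @export
detect_markers <- function(img, polarity = c("dark", "bright"),
                           expected_radius_px = c(4, 20),
                           max_markers = 12L,
                           threshold_quantile = NULL,
                           min_circularity = 0.6,
                           min_solidity = 0.8) {
  stopifnot(inherits(img, "sensor_image"))
  polarity <- match.arg(polarity)
  ch <- if ("B" %in% img$channel_names) "B" else img$channel_names[1]
  x <- get_channel(img, ch)
  npix <- length(x)
  rmin <- expected_radius_px[1]; rmax <- expected_radius_px[2]
  fin <- is.finite(x)
  if (is.null(threshold_quantile)) {
    # locate the marker intensity level by the area of one smallest marker,
    # then threshold halfway between it and the background (median) level
    q_ext <- min(0.25, max(pi * rmin^2 / npix, 1e-6))
    med <- stats::median(x[fin])
    tau <- if (polarity == "dark")
      (stats::quantile(x[fin], q_ext, names = FALSE) + med) / 2
    else
      (stats::quantile(x[fin], 1 - q_ext, names = FALSE) + med) / 2
  } else {
    tau <- if (polarity == "dark")
      stats::quantile(x[fin], threshold_quantile, names = FALSE)
    else
      stats::quantile(x[fin], 1 - threshold_quantile, names = FALSE)
  }
  mask <- if (polarity == "dark") fin & x < tau else fin & x > tau
  storage.mode(mask) <- "integer"
  lab <- EBImage::bwlabel(mask)
  nlab <- max(lab)
  obs <- list()
  if (nlab > 0) {
    idx <- which(lab > 0)
    labs <- lab[idx]
    rows <- (idx - 1L) %% nrow(lab) + 1L
    cols <- (idx - 1L) %/% nrow(lab) + 1L
    areas <- tabulate(labs, nbins = nlab)
    keep <- which(areas >= pi * rmin^2 & areas <= pi * rmax^2)
    for (k in keep) {
      sel <- labs == k
      r <- rows[sel]; c <- cols[sel]
      A <- areas[k]
      # digital perimeter: blob pixels with at least one 4-neighbour outside
      inblob <- matrix(FALSE, nrow(lab), ncol(lab))
      inblob[cbind(r, c)] <- TRUE
      on_edge <- r == 1 | r == nrow(lab) | c == 1 | c == ncol(lab)
      nb <- !on_edge &
        inblob[cbind(pmax(r - 1L, 1L), c)] &
        inblob[cbind(pmin(r + 1L, nrow(lab)), c)] &
        inblob[cbind(r, pmax(c - 1L, 1L))] &
        inblob[cbind(r, pmin(c + 1L, ncol(lab)))]
      P <- sum(!nb)
      circ <- 4 * pi * A / P^2
      if (circ < min_circularity) next
      sol <- blob_solidity(r, c, A, P)
      if (sol < min_solidity) next
      v <- x[cbind(r, c)]
      w <- if (polarity == "dark") pmax(tau - v, 0) else pmax(v - tau, 0)
      if (sum(w) <= 0) w <- rep(1, length(v))
      center <- c(sum(r * w), sum(c * w)) / sum(w)
      obs[[length(obs) + 1L]] <- list(
        center = center,
        radius = sqrt(A / pi),
        score = min(1, circ),
        contrast = mean(w),
        source_channel = ch)
    }
  }
  if (length(obs)) {
    ord <- order(vapply(obs, `[[`, 0, "score"),
                 vapply(obs, `[[`, 0, "contrast"), decreasing = TRUE)
    obs <- obs[ord]
    if (length(obs) > max_markers) obs <- obs[seq_len(max_markers)]
  }
  if (length(obs) < 4) {
    cond <- structure(
      class = c("aerophen_registration_infeasible", "error", "condition"),
      list(message = sprintf(
        "only %d marker(s) detected (>= 4 needed); supply manual overrides",
        length(obs)),
        call = sys.call(-1), markers = obs))
    stop(cond)
  }
  obs
}

# solidity = pixel area / convex hull area, the hull taken through pixel
# centers and dilated by half the digital perimeter (Pick-style correction
# so that a perfect disk scores ~1)
blob_solidity <- function(r, c, A, P) {
  if (length(r) < 4) return(1)
  pts <- cbind(r, c)
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  n <- nrow(hp)
  if (n < 3) return(1)
  x <- hp[, 1]; y <- hp[, 2]
  hull_area <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  min(1, A / (hull_area + P / 2 + 1))
}

#' Order detected markers to match a set of reference positions
#'
#' Establishes the correspondence between detections in one sensor frame
#' and known layout positions (or detections from another sensor) by
#' sorting both sets by angle around their centroid and choosing the
#' cyclic shift minimizing the summed squared distance after centering and
#' scale normalization. Valid for markers placed around the field
#' perimeter under mild projective distortion (which preserves their
#' cyclic order).
#'
#' @param markers List of marker observations (see [detect_markers()]).
#' @param reference `n x 2` matrix of reference (row, col) positions.
#' @return The markers reordered so element `i` corresponds to
#'   `reference[i, ]`.
#' @export
match_markers <- function(markers, reference) {
  reference <- rbind2cols(reference)
  n <- nrow(reference)
  if (length(markers) < n)
    stop(sprintf("need %d markers to match reference, have %d", n,
                 length(markers)), call. = FALSE)
  markers <- markers[seq_len(n)]  # already score-sorted
  det <- t(vapply(markers, `[[`, numeric(2), "center"))
  norm_set <- function(p) {
    ctr <- colMeans(p)
    q <- sweep(p, 2, ctr)
    s <- mean(sqrt(rowSums(q^2)))
    if (s > 0) q / s else q
  }
  ang_order <- function(p) order(atan2(p[, 2], p[, 1]))
  dn <- norm_set(det); rn <- norm_set(reference)
  od <- ang_order(dn); orr <- ang_order(rn)
  best <- NULL; best_cost <- Inf
  for (shift in 0:(n - 1)) {
    perm <- od[(seq_len(n) + shift - 1L) %% n + 1L]
    cost <- sum((dn[perm, ] - rn[orr, ])^2)
    if (cost < best_cost) { best_cost <- cost; best <- perm }
  }
  out <- vector("list", n)
  out[orr] <- markers[best]
  out
}

#' Read manual marker overrides
#'
#' Reads a CSV of `campaign, sensor, marker_id, row, col` and returns, for
#' one campaign/sensor, a list of marker observations that replaces the
#' automatic detections (mirroring manual center identification when the
#' automatic path fails).
#'
#' @param path CSV path.
#' @param campaign,sensor Labels to filter on.
#' @return List of marker observations (score absent), ordered by
#'   `marker_id`, or `NULL` if the file holds no rows for this
#'   campaign/sensor.
#' @export
read_marker_overrides <- function(path, campaign, sensor) {
  ov <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("campaign", "sensor", "marker_id", "row", "col")
  if (!all(need %in% names(ov)))
    stop("override CSV must have columns campaign, sensor, marker_id, row, col",
         call. = FALSE)
  ov <- ov[ov$campaign == campaign & ov$sensor == sensor, , drop = FALSE]
  if (!nrow(ov)) return(NULL)
  ov <- ov[order(ov$marker_id), ]
  lapply(seq_len(nrow(ov)), function(i)
    list(center = c(ov$row[i], ov$col[i]), radius = NA_real_,
         score = NA_real_, source_channel = "manual"))
}
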