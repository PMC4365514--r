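#' Parse and format plot polygons
#'
#' Plot polygons are stored as a vertex list string `"x1 y1; x2 y2; ..."`
#' in AoI-frame metres (x along columns, y along rows).
#'
#' @param s Polygon string.
#' @return `n x 2` matrix with columns `x`, `y` (metres).
#' @export
parse_polygon <- function(s) {
  parts <- strsplit(trimws(unlist(strsplit(s, ";"))), "\\s+")
  m <- do.call(rbind, lapply(parts, as.numeric))
  colnames(m) <- c("x", "y")
  m
}

#' @rdname parse_polygon
#' @param poly `n x 2` matrix of x/y vertices in metres.
#' @export
format_polygon <- function(poly) {
  paste(apply(poly, 1, function(p) paste(format(p, trim = TRUE), collapse = " ")),
        collapse = "; ")
}

# even-odd crossing test; px/py are point vectors, poly an n x 2 matrix
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross & is.finite(cross))
    j <- i
  }
  inside
}

#' Rasterize a plot map onto the AoI pixel grid
#'
#' Labels every AoI pixel with the index of the plot whose polygon
#' contains the pixel center (0 = background). Pixel centers sit at
#' integer (row, col); the center of pixel (r, c) is at metres
#' `((c - 0.5) * g, (r - 0.5) * g)`.
#'
#' @param map Data frame with columns `plot_id` and `polygon` (vertex
#'   strings, see [parse_polygon()]); typically a trial design from
#'   [generate_design()].
#' @param aoi_shape Integer `c(H, W)`.
#' @param ground_pixel_m Ground size of one AoI pixel in metres.
#' @return Integer `H x W` matrix of plot indices (row numbers of `map`),
#'   with attribute `plot_ids` giving the id for each index. Overlapping
#'   polygons raise an error naming the offending pair.
#' @export
rasterize_plot_map <- function(map, aoi_shape, ground_pixel_m) {
  H <- as.integer(aoi_shape[1]); W <- as.integer(aoi_shape[2])
  lab <- matrix(0L, H, W)
  if (!nrow(map)) {
    attr(lab, "plot_ids") <- character(0)
    return(lab)
  }
  g <- ground_pixel_m
  for (i in seq_len(nrow(map))) {
    poly <- parse_polygon(map$polygon[i])
    # candidate pixels: bounding box only
    c_lo <- max(1L, floor(min(poly[, "x"]) / g))
    c_hi <- min(W, ceiling(max(poly[, "x"]) / g) + 1L)
    r_lo <- max(1L, floor(min(poly[, "y"]) / g))
    r_hi <- min(H, ceiling(max(poly[, "y"]) / g) + 1L)
    if (c_lo > c_hi || r_lo > r_hi) next
    rs <- rep(r_lo:r_hi, times = c_hi - c_lo + 1L)
    cs <- rep(c_lo:c_hi, each = r_hi - r_lo + 1L)
    inside <- point_in_polygon((cs - 0.5) * g, (rs - 0.5) * g, poly)
    if (!any(inside)) next
    idx <- cbind(rs[inside], cs[inside])
    clash <- lab[idx] != 0L
    if (any(clash)) {
      other <- lab[idx][which(clash)[1]]
      stop(sprintf("overlapping plot polygons: '%s' and '%s'",
                   map$plot_id[other], map$plot_id[i]), call. = FALSE)
    }
    lab[idx] <- i
  }
  attr(lab, "plot_ids") <- as.character(map$plot_id)
  lab
}

#' Skewness of a pixel-value distribution
#'
#' Third standardized moment with population (1/n) moments and no bias
#' correction: `s = m3 / m2^(3/2)`. Zero for a distribution symmetric
#' about its mean; positive values on plot NDVI distributions flag plots
#' with sparse canopy (a long soil tail below the plant mode).
#'
#' @param x Numeric vector, `n >= 2`, nonzero variance.
#' @return Skewness (dimensionless).
#' @examples
#' skewness(c(0, 0, 1))  # 1/sqrt(2)
#' @export
skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2) stop("skewness needs at least 2 values", call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) stop("undefined skewness: zero variance", call. = FALSE)
  mean((x - m)^3) / m2^1.5
}

skewness_or_na <- function(x) tryCatch(skewness(x), error = function(e) NA_real_)

#' Extract per-plot traits from a co-registered image stack
#'
#' For every labelled plot computes: canopy cover `cc` (fraction of plant
#' pixels among valid pixels), `ndvi_plot` (median NDVI over all valid
#' pixels) and `ndvi_plant` (median over plant pixels only),
#' the corresponding skewness values, the canopy temperature `t_c`
#' (median thermal signal over all valid pixels -- the thermal resolution
#' does not support plant/soil segmentation, so the plot signal is a
#' plant/soil mixture), and `dt = t_c - air_temp`. Negative `dt` means the
#' canopy is cooler than the ambient air (transpiration cooling).
#'
#' @param ndvi An `ndvi_raster` in the AoI frame.
#' @param mask A `segmentation_mask` in the AoI frame.
#' @param labels Labelled raster from [rasterize_plot_map()].
#' @param thermal Optional `H x W` matrix of temperatures (deg C) in the
#'   AoI frame.
#' @param air_temp Optional air temperature at capture time (deg C), one
#'   value for the whole campaign (single on-site weather station).
#' @param campaign_id Campaign label for the output rows.
#' @param aggregate `"median"` (default) or `"mean"` for NDVI and
#'   temperature summaries.
#' @param min_valid_fraction Plots with a smaller share of valid pixels
#'   are flagged (`low_coverage`) but kept.
#' @return Data frame with one row per plot: `plot_id`, `campaign_id`,
#'   `cc`, `ndvi_plot`, `ndvi_plant`, `skew_plot`, `skew_plant`, `t_c`,
#'   `dt`, `n_pixels`, `n_valid_pixels`, `n_plant_pixels`,
#'   `low_coverage`, `error`. A plot with zero valid pixels yields an
#'   error record (all traits `NA`) and the run continues.
#' @export
extract_plot_traits <- function(ndvi, mask, labels, thermal = NULL,
                                air_temp = NULL, campaign_id = NULL,
                                aggregate = c("median", "mean"),
                                min_valid_fraction = 0.8) {
  stopifnot(inherits(ndvi, "ndvi_raster"), inherits(mask, "segmentation_mask"))
  aggregate <- match.arg(aggregate)
  agg <- if (aggregate == "median") stats::median else mean
  if (is.null(campaign_id)) campaign_id <- ndvi$campaign_id
  plot_ids <- attr(labels, "plot_ids")
  n_plots <- length(plot_ids)
  out <- vector("list", n_plots)
  for (i in seq_len(n_plots)) {
    sel <- which(labels == i)
    n_pix <- length(sel)
    valid <- sel[mask$valid[sel] & is.finite(ndvi$values[sel])]
    rec <- list(plot_id = plot_ids[i], campaign_id = campaign_id,
                cc = NA_real_, ndvi_plot = NA_real_, ndvi_plant = NA_real_,
                skew_plot = NA_real_, skew_plant = NA_real_,
                t_c = NA_real_, dt = NA_real_,
                n_pixels = n_pix, n_valid_pixels = length(valid),
                n_plant_pixels = 0L, low_coverage = FALSE, error = NA_character_)
    if (length(valid) == 0) {
      rec$error <- "no valid pixels in plot"
      out[[i]] <- rec
      next
    }
    plant <- valid[mask$plant[valid]]
    rec$n_plant_pixels <- length(plant)
    rec$cc <- length(plant) / length(valid)
    rec$ndvi_plot <- agg(ndvi$values[valid])
    rec$skew_plot <- skewness_or_na(ndvi$values[valid])
    if (length(plant)) {
      rec$ndvi_plant <- agg(ndvi$values[plant])
      rec$skew_plant <- skewness_or_na(ndvi$values[plant])
    }
    if (!is.null(thermal)) {
      tv <- thermal[valid]
      tv <- tv[is.finite(tv)]
      if (length(tv)) {
        rec$t_c <- agg(tv)
        if (!is.null(air_temp)) rec$dt <- rec$t_c - air_temp
      }
    }
    rec$low_coverage <- length(valid) / n_pix < min_valid_fraction
    out[[i]] <- rec
  }
  do.call(rbind, lapply(out, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Assemble the seasonal long-format trait table
#'
#' Joins per-plot trait records with the design (genotype, rows, block)
#' and the campaign metadata (thermal time), and pivots the traits to long
#' format ready for the statistics functions.
#'
#' @param records Data frame of rows from [extract_plot_traits()] (several
#'   campaigns stacked).
#' @param design Trial design data frame with `plot_id`, `genotype`,
#'   `rows`, `block`.
#' @param campaigns Data frame with `campaign_id` and `tt` (thermal time,
#'   deg C d).
#' @param traits Which trait columns to pivot.
#' @return Long data frame with columns `plot_id`, `genotype`, `rows`,
#'   `block`, `campaign_id`, `tt`, `trait`, `value`.
#' @export
seasonal_table <- function(records, design,
                           campaigns,
                           traits = c("cc", "ndvi_plot", "ndvi_plant",
                                      "skew_plot", "t_c", "dt")) {
  if (!nrow(records)) {
    return(data.frame(plot_id = character(0), genotype = character(0),
                      rows = integer(0), block = character(0),
                      campaign_id = character(0), tt = numeric(0),
                      trait = character(0), value = numeric(0)))
  }
  unknown <- setdiff(unique(records$campaign_id), campaigns$campaign_id)
  if (length(unknown))
    stop(sprintf("records reference unknown campaign(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  m <- merge(records, design[, c("plot_id", "genotype", "rows", "block")],
             by = "plot_id")
  m <- merge(m, campaigns[, c("campaign_id", "tt")], by = "campaign_id")
  long <- do.call(rbind, lapply(traits, function(tr) {
    data.frame(plot_id = m$plot_id, genotype = m$genotype, rows = m$rows,
               block = m$block, campaign_id = m$campaign_id, tt = m$tt,
               trait = tr, value = m[[tr]], stringsAsFactors = FALSE)
  }))
  long[order(long$trait, long$campaign_id, long$plot_id), , drop = FALSE]
}
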