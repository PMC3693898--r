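# Recombination between block centers.  A map holds one recombination
# fraction theta per adjacent block pair; theta = 0.5 marks a chromosome
# break (unlinked).  Crossovers have no interference: meiosis samples an
# independent Bernoulli(theta_i) switch at each interval.

new_recomb_map <- function(centers_bp, chrom, theta) {
  stopifnot(length(theta) == length(centers_bp) - 1 || length(centers_bp) <= 1)
  if (any(theta < 0 | theta > 0.5)) {
    stop("recombination fractions must lie in [0, 0.5]; for an unlinked ",
         "interval use exactly 0.5")
  }
  structure(
    list(centers_bp = centers_bp, chrom = as.character(chrom), theta = theta),
    class = "recomb_map"
  )
}

#' @export
print.recomb_map <- function(x, ...) {
  cat(sprintf("<recomb_map> %d block center(s), %d interval(s), %d chromosome(s)\n",
              length(x$centers_bp), length(x$theta), length(unique(x$chrom))))
  invisible(x)
}

#' Uniform recombination map
#'
#' All `n_blocks - 1` adjacent intervals get the same recombination
#' fraction, mirroring the fixed-rate default of coalescent sequence
#' simulators.
#'
#' @param theta Recombination fraction in `[0, 0.5]`.
#' @param n_blocks Number of blocks.
#' @param chrom Chromosome label(s), recycled to `n_blocks`.
#' @return A `recomb_map`.
#' @export
fixed_map <- function(theta, n_blocks, chrom = "1") {
  if (theta < 0 || theta > 0.5) stop("theta must lie in [0, 0.5]")
  if (n_blocks < 1) stop("n_blocks must be >= 1")
  new_recomb_map(
    centers_bp = seq_len(n_blocks),
    chrom = rep_len(chrom, n_blocks),
    theta = rep(theta, max(n_blocks - 1L, 0L))
  )
}

#' Haldane map distance from a recombination fraction
#'
#' `d_cM = -50 * log(1 - 2 * theta)`, assuming no crossover interference.
#'
#' @param theta Recombination fraction(s) in `[0, 0.5)`.
#' @return Distance(s) in centimorgans.
#' @export
haldane_theta_to_cm <- function(theta) {
  if (any(theta < 0)) stop("theta must be non-negative")
  if (any(theta >= 0.5)) stop("theta >= 0.5 has infinite map distance")
  -50 * log(1 - 2 * theta)
}

#' Recombination fraction from a Haldane map distance
#'
#' `theta = (1 - exp(-2 d / 100)) / 2`; inverse of [haldane_theta_to_cm()].
#'
#' @param d_cm Distance(s) in centimorgans, >= 0.
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @export
haldane_cm_to_theta <- function(d_cm) {
  if (any(d_cm < 0)) stop("map distance must be non-negative")
  (1 - exp(-2 * d_cm / 100)) / 2
}

#' Build a recombination map from a hotspot table
#'
#' For each pair of adjacent block centers on the same chromosome, the
#' genetic distance is the sum, over hotspots whose midpoint lies between
#' the two centers, of `rate_cM_Mb * width / 1e6` cM, where the rate is the
#' hotspot's (maximum) rate and the width is the hotspot's own
#' `end - start` extent; the distance is then converted to a recombination
#' fraction with the inverse Haldane function.  Adjacent centers on
#' different chromosomes get theta = 0.5 (unlinked).
#'
#' @param hotspots `data.frame` with columns `chrom`, `start`, `end`
#'   (1-based inclusive bp) and `rate_cM_Mb` (>= 0).  Intervals must not
#'   overlap within a chromosome.
#' @param block_centers `data.frame` with columns `chrom` and `center_bp`
#'   (e.g. from [pool_block_centers()]); centers must be sorted by position
#'   within each chromosome.
#' @return A `recomb_map`.
#' @export
map_from_hotspots <- function(hotspots, block_centers) {
  need <- c("chrom", "start", "end", "rate_cM_Mb")
  if (!all(need %in% names(hotspots))) {
    stop("hotspot table needs columns chrom, start, end, rate_cM_Mb")
  }
  if (any(hotspots$rate_cM_Mb < 0)) stop("negative hotspot rate")
  if (any(hotspots$end < hotspots$start)) stop("hotspot end before start")
  for (ch in unique(hotspots$chrom)) {
    h <- hotspots[hotspots$chrom == ch, ]
    h <- h[order(h$start), ]
    if (nrow(h) > 1 && any(h$start[-1] <= h$end[-nrow(h)])) {
      stop(sprintf("overlapping hotspots on chromosome %s", ch))
    }
  }
  nb <- nrow(block_centers)
  ch <- as.character(block_centers$chrom)
  pos <- block_centers$center_bp
  same <- ch[-nb] == ch[-1]
  if (any(same & diff(pos) <= 0)) {
    stop("block centers must be sorted within each chromosome")
  }
  mid <- (hotspots$start + hotspots$end) / 2
  cm <- hotspots$rate_cM_Mb * (hotspots$end - hotspots$start) / 1e6
  theta <- numeric(max(nb - 1L, 0L))
  for (i in seq_along(theta)) {
    if (!same[i]) {
      theta[i] <- 0.5
    } else {
      sel <- hotspots$chrom == ch[i] & mid > pos[i] & mid <= pos[i + 1]
      theta[i] <- haldane_cm_to_theta(sum(cm[sel]))
    }
  }
  new_recomb_map(pos, ch, theta)
}

#' Chromosome index of each block in a map
#'
#' Blocks separated by a theta = 0.5 interval or a chromosome label change
#' belong to different chromosomes.
#'
#' @param rmap A `recomb_map`.
#' @return Integer vector, one entry per block, starting at 1.
#' @keywords internal
map_chromosomes <- function(rmap) {
  nb <- length(rmap$centers_bp)
  if (nb == 0) return(integer(0))
  breaks <- if (nb > 1) {
    rmap$theta >= 0.5 | rmap$chrom[-nb] != rmap$chrom[-1]
  } else {
    logical(0)
  }
  cumsum(c(1L, as.integer(breaks)))
}

#' Cumulative map position of each block
#'
#' Centimorgans from the first block of each chromosome, accumulating
#' Haldane-converted interval distances; restarts at 0 on every chromosome
#' break.
#'
#' @param rmap A `recomb_map`.
#' @return Numeric vector, one entry per block.
#' @export
map_positions_cm <- function(rmap) {
  nb <- length(rmap$centers_bp)
  if (nb == 0) return(numeric(0))
  chrom <- map_chromosomes(rmap)
  pos <- numeric(nb)
  for (i in seq_len(nb - 1L)) {
    pos[i + 1L] <- if (chrom[i + 1L] != chrom[i]) {
      0
    } else {
      pos[i] + haldane_theta_to_cm(rmap$theta[i])
    }
  }
  pos
}
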