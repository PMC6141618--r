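#' Convert normalized detector samples to a map memory index
#'
#' Each normalized difference value is quantized to the nearest contour
#' level (clamped to the level range), and the two level indices are
#' combined into the zero-based memory index
#' `h_index * n_v_levels + v_index` of the ordered map array.
#'
#' @param sample A data.frame with columns `h_norm`, `v_norm` (one or more
#'   rows), or a length-2 numeric `c(h_norm, v_norm)`.
#' @param map A `contour_map` from [build_map()].
#' @return Integer-valued numeric vector of zero-based indices, with
#'   attribute `clamped` (logical vector: signal fell outside the level
#'   range and was clamped).
#' @export
signal_to_index <- function(sample, map) {
  stopifnot(inherits(map, "contour_map"))
  if (is.numeric(sample) && is.null(dim(sample)))
    sample <- data.frame(h_norm = sample[1], v_norm = sample[2])
  hl <- map$h_levels; vl <- map$v_levels
  hi <- round((sample$h_norm - hl$levels[1]) / hl$spacing)
  vi <- round((sample$v_norm - vl$levels[1]) / vl$spacing)
  clamped <- hi < 0 | hi > hl$n_levels - 1 | vi < 0 | vi > vl$n_levels - 1
  hi <- clamp(hi, 0, hl$n_levels - 1)
  vi <- clamp(vi, 0, vl$n_levels - 1)
  structure(hi * vl$n_levels + vi, clamped = clamped)
}

# Decoded position tables for fast vectorized lookup, with placeholder
# entries resolved to the nearest valid neighbor in (h, v) index space
# (Euclidean on index offsets; ties broken toward the smaller linear
# index). Cached on the map via an attribute-free recomputation by callers
# that loop.
map_position_table <- function(map) {
  stopifnot(inherits(map, "contour_map"))
  if (!is.null(map$cache) && !is.null(map$cache$tab)) return(map$cache$tab)
  nh <- map$h_levels$n_levels; nv <- map$v_levels$n_levels
  dec <- unpack_entry(map$entries, map$region)
  miss <- map$entries == PLACEHOLDER
  if (all(miss)) stop("unusable map: every entry is a placeholder")
  x <- dec$x; y <- dec$y
  if (any(miss)) {
    # valid-entry mask as an nv x nh matrix (v level is the fast axis)
    vm <- matrix(!miss, nrow = nv, ncol = nh)
    for (k in which(miss)) {
      kv <- (k - 1L) %% nv + 1L
      kh <- (k - 1L) %/% nv + 1L
      r <- 2L
      pick <- NA_integer_
      repeat {
        rows <- max(1L, kv - r):min(nv, kv + r)
        cols <- max(1L, kh - r):min(nh, kh + r)
        sub <- vm[rows, cols, drop = FALSE]
        w <- which(sub)
        if (length(w)) {
          sr <- rows[(w - 1L) %% length(rows) + 1L]
          sc <- cols[(w - 1L) %/% length(rows) + 1L]
          d2 <- (sr - kv)^2 + (sc - kh)^2
          best <- which(d2 == min(d2))
          lin <- (sc[best] - 1L) * nv + sr[best]  # 1-based entry index
          pick <- min(lin)                        # tie -> smaller index
          if (min(d2) <= r^2) break   # a radius-r window holds the true NN
        }
        if (length(rows) == nv && length(cols) == nh) break
        r <- r * 2L
      }
      x[k] <- x[pick]; y[k] <- y[pick]
    }
  }
  tab <- list(x = x, y = y, miss = miss, nh = nh, nv = nv,
              h0 = map$h_levels$levels[1], dh = map$h_levels$spacing,
              v0 = map$v_levels$levels[1], dv = map$v_levels$spacing)
  if (!is.null(map$cache)) map$cache$tab <- tab
  tab
}

#' Retrieve a tracked position from the map
#'
#' @param index Zero-based memory index (vectorized), as produced by
#'   [signal_to_index()].
#' @param map A `contour_map`.
#' @return Data.frame with columns `x`, `y` (nm) and `miss` (logical: the
#'   addressed entry was a placeholder and the nearest valid neighbor in
#'   index space was returned instead).
#' @export
lookup_position <- function(index, map) {
  stopifnot(inherits(map, "contour_map"))
  index <- as.numeric(index)
  if (any(index < 0 | index >= length(map$entries)))
    stop("index out of bounds")
  tab <- map_position_table(map)
  i1 <- as.integer(index) + 1L
  data.frame(x = tab$x[i1], y = tab$y[i1], miss = tab$miss[i1])
}

#' Track a detector sample stream through the map
#'
#' Converts every sample to a looked-up position and averages the positions
#' over non-overlapping blocks of `block_size` samples (the
#' digitization-level averaging that trades rate for noise), producing
#' tracked positions at `sample_rate / block_size` scaled by a constant
#' processing-overhead factor: the default 0.86 reproduces the realized
#' 8.6 kHz tracking rate from 1 MHz digitization with 100-point averaging.
#' A trailing partial block is discarded.
#'
#' @param samples Data.frame with columns `t`, `h_norm`, `v_norm` (from
#'   [sample_stream()]).
#' @param map A `contour_map`.
#' @param block_size Samples per block (default 100).
#' @param sample_rate Digitization rate in Hz; inferred from timestamps if
#'   `NULL`.
#' @param overhead Rate overhead factor (default 0.86).
#' @return A `tracked_trace`: data.frame with columns `t`, `x`, `y` plus
#'   attributes `nominal_rate`, `block_size`, `misses` (count of placeholder
#'   lookups), `clamped` (count of clamped samples).
#' @export
track_stream <- function(samples, map, block_size = 100, sample_rate = NULL,
                         overhead = 0.86) {
  stopifnot(inherits(map, "contour_map"))
  samples <- as.data.frame(samples)
  if (nrow(samples) == 0L) stop("empty sample stream")
  if (nrow(samples) < block_size)
    stop("need at least one full block of samples")
  if (is.null(sample_rate)) {
    if (nrow(samples) < 2L) stop("cannot infer sample_rate from one sample")
    sample_rate <- 1 / stats::median(diff(samples$t))
  }
  idx <- signal_to_index(samples, map)
  tab <- map_position_table(map)
  i1 <- as.integer(idx) + 1L
  n_blocks <- nrow(samples) %/% block_size
  keep <- seq_len(n_blocks * block_size)
  grp <- rep(seq_len(n_blocks), each = block_size)
  x <- as.numeric(rowsum(tab$x[i1[keep]], grp)) / block_size
  y <- as.numeric(rowsum(tab$y[i1[keep]], grp)) / block_size
  nominal_rate <- sample_rate / block_size * overhead
  trace <- data.frame(t = samples$t[1] + (seq_len(n_blocks) - 1L) / nominal_rate,
                      x = x, y = y)
  structure(trace, nominal_rate = nominal_rate, block_size = block_size,
            misses = sum(tab$miss[i1]), clamped = sum(attr(idx, "clamped")),
            class = c("tracked_trace", "data.frame"))
}
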