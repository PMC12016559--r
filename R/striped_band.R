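#' Band configuration for the striped layout
#'
#' A band of `width` W cells per row is stored across `segments`
#' s_bar = W / `lanes` registers of `lanes` p cells each. The striped map
#' places in-band offset x (0-based) in register `x %% s_bar`, lane
#' `x %/% s_bar`, so consecutive cells of one register are s_bar apart in
#' normal order -- this breaks the intra-register dependency chains of the
#' row recurrence. Correctness is independent of the lane count; the default
#' p = 16 emulates 128-bit registers of 8-bit lanes.
#'
#' @param width band width W, a positive multiple of `lanes`.
#' @param lanes emulated vector width p.
#' @return An object of class `band_config` with fields `width`, `lanes`,
#'   `segments`.
#' @examples
#' band_config(16, 4)
#' @export
band_config <- function(width, lanes = 16L) {
  if (!.is_count(width) || width < 1) stop("band width must be a positive integer")
  if (!.is_count(lanes) || lanes < 1) stop("lane count must be a positive integer")
  if (width %% lanes != 0)
    stop(sprintf("band width %d is not a multiple of the lane count %d",
                 as.integer(width), as.integer(lanes)))
  structure(list(width = as.integer(width), lanes = as.integer(lanes),
                 segments = as.integer(width %/% lanes)),
            class = "band_config")
}

#' @export
print.band_config <- function(x, ...) {
  cat(sprintf("<band_config> width %d = %d lanes x %d segments\n",
              x$width, x$lanes, x$segments))
  invisible(x)
}

.check_cfg <- function(cfg) {
  if (!inherits(cfg, "band_config"))
    stop("expected a 'band_config' object (see band_config())")
  cfg
}

#' Map an in-band offset to its striped slot
#'
#' @param offset 0-based in-band cell offset(s), in `[0, width)`.
#' @param cfg a [band_config()].
#' @return A list with 0-based components `register` and `lane`.
#' @examples
#' normal_to_striped(5, band_config(16, 4))  # register 1, lane 1
#' @export
normal_to_striped <- function(offset, cfg) {
  .check_cfg(cfg)
  if (any(!is.finite(offset)) || any(offset != floor(offset)) ||
      any(offset < 0) || any(offset >= cfg$width))
    stop(sprintf("offset must be an integer in [0, %d)", cfg$width))
  list(register = as.integer(offset %% cfg$segments),
       lane = as.integer(offset %/% cfg$segments))
}

#' Map a striped slot back to its in-band offset
#'
#' Inverse of [normal_to_striped()]: `offset = register + lane * segments`.
#'
#' @param register 0-based register index(es), in `[0, segments)`.
#' @param lane 0-based lane index(es), in `[0, lanes)`.
#' @param cfg a [band_config()].
#' @return Integer vector of 0-based in-band offsets.
#' @export
striped_to_normal <- function(register, lane, cfg) {
  .check_cfg(cfg)
  if (any(!is.finite(register)) || any(register != floor(register)) ||
      any(register < 0) || any(register >= cfg$segments))
    stop(sprintf("register must be an integer in [0, %d)", cfg$segments))
  if (any(!is.finite(lane)) || any(lane != floor(lane)) ||
      any(lane < 0) || any(lane >= cfg$lanes))
    stop(sprintf("lane must be an integer in [0, %d)", cfg$lanes))
  as.integer(register + lane * cfg$segments)
}

#' One striped band row
#'
#' Holds the W band cells of one row in striped layout (a `lanes` x
#' `segments` matrix whose column k is register k), together with the row's
#' bookkeeping: the band origin (query offset of in-band cell 0), the row
#' index along the reference, and the absolute score anchor at the band's
#' first cell from which absolute scores can be reconstructed out of the
#' stored differences.
#'
#' @param values numeric vector of length `width`, the cell payloads in
#'   normal (in-band) order.
#' @param cfg a [band_config()].
#' @param band_origin 0-based query offset of in-band cell 0.
#' @param row_index 0-based reference position of the row.
#' @param origin_score absolute alignment score at in-band cell 0.
#' @return An object of class `striped_row` with fields `registers` (the
#'   lane x register matrix), `cfg`, `band_origin`, `row_index`,
#'   `origin_score`.
#' @examples
#' r <- striped_row(0:15, band_config(16, 4))
#' r$registers[, 1]  # register 0 holds offsets 0, 4, 8, 12
#' @export
striped_row <- function(values, cfg, band_origin = 0L, row_index = 0L,
                        origin_score = 0) {
  .check_cfg(cfg)
  if (length(values) != cfg$width)
    stop(sprintf("values must have length %d (the band width)", cfg$width))
  m <- matrix(neg_inf_sentinel(), nrow = cfg$lanes, ncol = cfg$segments)
  for (t in seq_len(cfg$lanes)) {
    # lane t-1 traverses offsets (t-1)*segments .. t*segments - 1
    m[t, ] <- values[((t - 1) * cfg$segments + 1):(t * cfg$segments)]
  }
  structure(list(registers = m, cfg = cfg,
                 band_origin = as.integer(band_origin),
                 row_index = as.integer(row_index),
                 origin_score = origin_score),
            class = "striped_row")
}

#' Read a striped row back in normal (in-band) order
#'
#' Test and debugging helper; the production kernels never materialize this.
#'
#' @param row a [striped_row()].
#' @return Numeric vector of length `width` in normal order.
#' @export
striped_to_normal_values <- function(row) {
  if (!inherits(row, "striped_row")) stop("expected a 'striped_row'")
  as.vector(t(row$registers))
}

#' @export
print.striped_row <- function(x, ...) {
  cat(sprintf("<striped_row> j = %d, band origin %d, origin score %s\n",
              x$row_index, x$band_origin, format(x$origin_score)))
  cat("normal order:", format(striped_to_normal_values(x)), "\n")
  invisible(x)
}

#' Decide the band shift for the next row
#'
#' Compares the summed absolute scores of the band's first and last register
#' (strided samples of the row). A heavier first register pulls the band
#' left (shift 0, favouring a vertical gap), equality keeps it on the
#' diagonal (shift 1), a heavier last register pushes it right (shift 2,
#' favouring a horizontal gap). Sentinel cells participate with their
#' sentinel value.
#'
#' @param first_register_values,last_register_values numeric vectors of `p`
#'   lane scores.
#' @return 0, 1 or 2.
#' @examples
#' decide_shift(c(10, 10), c(3, 3))  # 0
#' decide_shift(c(7, 7), c(7, 7))    # 1
#' @export
decide_shift <- function(first_register_values, last_register_values) {
  if (length(first_register_values) != length(last_register_values))
    stop("register value vectors must have equal length")
  sf <- sum(first_register_values)
  sl <- sum(last_register_values)
  if (sf > sl) 0L else if (sf == sl) 1L else 2L
}

#' Striped move: re-layout the band for a shifted next row
#'
#' Shifts the row's normal-order content left by `shift` cells, filling the
#' vacated trailing cells with the sentinel, and advances the band origin --
#' realized purely on the striped registers as a rotation of the register
#' sequence by `shift` positions, with each wrapped register additionally
#' shifted by one lane slot and sentinel-filled in its last lane. The
#' normal-order array is never materialized; the work is O(segments)
#' register operations regardless of the shift.
#'
#' @param row a [striped_row()].
#' @param shift 0, 1 or 2 band cells.
#' @param cfg the row's [band_config()] (defaults to `row$cfg`).
#' @param neg_inf sentinel value for vacated cells.
#' @return A new `striped_row` with updated registers and `band_origin`.
#' @export
striped_move <- function(row, shift, cfg = row$cfg,
                         neg_inf = neg_inf_sentinel()) {
  if (!inherits(row, "striped_row")) stop("expected a 'striped_row'")
  .check_cfg(cfg)
  if (!.is_count(shift) || !(shift %in% 0:2))
    stop("shift must be 0, 1 or 2")
  shift <- as.integer(shift)
  out <- row
  out$band_origin <- row$band_origin + shift
  if (shift == 0L) return(out)
  sb <- cfg$segments
  p <- cfg$lanes
  old <- row$registers
  new <- matrix(neg_inf, nrow = p, ncol = sb)
  for (k in seq_len(sb)) {             # destination register k-1
    tot <- (k - 1L) + shift
    src <- tot %% sb                   # source register (0-based)
    wrap <- tot %/% sb                 # lane-shift count (0 for unwrapped,
    if (wrap < p) {                    # 1 per wrap; sentinel fill at the end)
      keep <- p - wrap
      new[seq_len(keep), k] <- old[(wrap + 1L):p, src + 1L]
    }
  }
  out$registers <- new
  out
}
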