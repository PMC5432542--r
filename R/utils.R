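# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a typed condition
#'
#' All pipeline errors carry a `wheatdens_*` condition class so callers can
#' distinguish degenerate inputs from genuine failures.
#'
#' @noRd
wd_error <- function(class, message, ...) {
  stop(structure(
    class = c(class, "wheatdens_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

wd_assert <- function(cond, class, message) {
  if (!isTRUE(cond)) wd_error(class, message)
  invisible(TRUE)
}

#' Shift a matrix by (dr, dc), padding with `fill`
#' @noRd
shift_mat <- function(m, dr, dc, fill = 0L) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- max(1L, 1L + dr):min(h, h + dr)
  cs <- max(1L, 1L + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

# 8-neighbour offsets (row, col)
NEIGH8 <- cbind(
  dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
  dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
)

#' Count foreground 8-neighbours of every pixel of a logical matrix
#' @noRd
neighbour_count8 <- function(m) {
  mi <- matrix(as.integer(m), nrow(m), ncol(m))
  acc <- matrix(0L, nrow(m), ncol(m))
  for (k in seq_len(nrow(NEIGH8))) {
    acc <- acc + shift_mat(mi, NEIGH8[k, 1L], NEIGH8[k, 2L], 0L)
  }
  acc
}

#' Deterministic sub-seed derivation (kept below .Machine$integer.max)
#' @noRd
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 16807) %% 2147483647)
}
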