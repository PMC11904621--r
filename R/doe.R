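# Joe-Kuo direction-number table (new-joe-kuo-6 convention) for dimensions
# 2..21; dimension 1 is the van der Corput sequence in base 2. Each row:
# degree s of the primitive polynomial, coefficient number a, and the initial
# direction integers m_1..m_s.
sobol_table <- list(
  list(s = 1, a = 0,  m = c(1)),
  list(s = 2, a = 1,  m = c(1, 3)),
  list(s = 3, a = 1,  m = c(1, 3, 1)),
  list(s = 3, a = 2,  m = c(1, 1, 1)),
  list(s = 4, a = 1,  m = c(1, 1, 3, 3)),
  list(s = 4, a = 4,  m = c(1, 3, 5, 13)),
  list(s = 5, a = 2,  m = c(1, 1, 5, 5, 17)),
  list(s = 5, a = 4,  m = c(1, 1, 5, 5, 5)),
  list(s = 5, a = 7,  m = c(1, 1, 7, 11, 19)),
  list(s = 5, a = 11, m = c(1, 1, 5, 1, 1)),
  list(s = 5, a = 13, m = c(1, 1, 1, 3, 11)),
  list(s = 5, a = 14, m = c(1, 3, 5, 5, 31)),
  list(s = 6, a = 1,  m = c(1, 3, 3, 9, 7, 49)),
  list(s = 6, a = 13, m = c(1, 1, 1, 15, 21, 21)),
  list(s = 6, a = 16, m = c(1, 3, 1, 13, 27, 49)),
  list(s = 6, a = 19, m = c(1, 1, 1, 15, 7, 5)),
  list(s = 6, a = 22, m = c(1, 3, 1, 3, 25, 31)),
  list(s = 6, a = 25, m = c(1, 3, 3, 9, 7, 11)),
  list(s = 7, a = 1,  m = c(1, 1, 5, 13, 11, 35, 127)),
  list(s = 7, a = 4,  m = c(1, 3, 5, 5, 1, 15, 29))
)

sobol_directions <- function(dim, nbits) {
  v <- integer(nbits)
  if (dim == 1) {
    for (k in seq_len(nbits)) v[k] <- bitwShiftL(1L, nbits - k)
    return(v)
  }
  e <- sobol_table[[dim - 1]]
  s <- e$s
  m <- as.integer(e$m)
  a <- as.integer(e$a)
  for (k in seq_len(min(s, nbits))) v[k] <- bitwShiftL(m[k], nbits - k)
  if (nbits > s) {
    for (k in (s + 1):nbits) {
      vk <- bitwXor(v[k - s], bitwShiftR(v[k - s], s))
      for (i in seq_len(s - 1)) {
        if (bitwAnd(bitwShiftR(a, s - 1 - i), 1L) == 1L)
          vk <- bitwXor(vk, v[k - i])
      }
      v[k] <- vk
    }
  }
  v
}

#' Unscrambled Sobol sequence points
#'
#' Deterministic base-2 Sobol points by the Gray-code construction with
#' Joe-Kuo direction numbers. `skip = 1` (default) drops the initial
#' all-zeros point, so the sequence starts at (0.5, ..., 0.5). Identical
#' `d` and `skip` always reproduce the same points; no random seed is
#' involved.
#'
#' @param d dimension (1 to 21 with the embedded direction table).
#' @param n number of points (>= 1).
#' @param skip leading sequence elements to drop.
#' @return n x d matrix of points in `[0, 1)^d`.
#' @export
sobol_points <- function(d, n, skip = 1) {
  stopifnot(d >= 1, n >= 1, skip >= 0)
  if (d > length(sobol_table) + 1)
    stop("sobol_points: embedded direction table covers d <= ",
         length(sobol_table) + 1)
  nbits <- 31L
  denom <- 2^nbits
  V <- vapply(seq_len(d), sobol_directions, integer(nbits), nbits = nbits)
  X <- matrix(0, n, d)
  state <- integer(d)
  total <- skip + n
  for (i in seq_len(total - 1)) {
    # Gray-code bit flipped between i-1 and i: lowest zero bit of i-1
    cbit <- 1L
    ii <- i - 1L
    while (bitwAnd(ii, 1L) == 1L) { ii <- bitwShiftR(ii, 1L); cbit <- cbit + 1L }
    state <- bitwXor(state, V[cbit, ])
    if (i >= skip) X[i - skip + 1, ] <- state / denom
  }
  if (skip == 0) X[1, ] <- 0   # explicit: the first element is the origin
  X
}

#' Build a Sobol experimental design with train/validation/test blocks
#'
#' Draws `n_train + n_valid + n_test` points of one continued Sobol sequence
#' in `[0,1]^d`, maps them affinely to the bounds of `space`, and labels the
#' contiguous blocks in order train, valid, test. The validation and test
#' blocks are literally the next points of the same sequence, not independent
#' designs.
#'
#' @param space a `pw_space`.
#' @param n_train,n_valid,n_test block sizes (>= 1).
#' @param skip leading Sobol elements to drop (default 1).
#' @return An object of class `pw_design`: list with `Theta` (physical
#'   units), `U` (unit cube), `segment` (factor), `space`.
#' @export
make_design <- function(space, n_train, n_valid = 100, n_test = 100,
                        skip = 1) {
  stopifnot(n_train >= 1, n_valid >= 1, n_test >= 1)
  if (any(space$upper - space$lower <= 0))
    stop("make_design: degenerate bounds")
  n <- n_train + n_valid + n_test
  U <- sobol_points(space$d, n, skip = skip)
  Theta <- sweep(sweep(U, 2, space$upper - space$lower, `*`), 2,
                 space$lower, `+`)
  colnames(Theta) <- colnames(U) <- space$names
  segment <- factor(rep(c("train", "valid", "test"),
                        c(n_train, n_valid, n_test)),
                    levels = c("train", "valid", "test"))
  structure(list(Theta = Theta, U = U, segment = segment, space = space),
            class = "pw_design")
}

#' Extract one block of a design
#' @param design a `pw_design`.
#' @param which `"train"`, `"valid"` or `"test"`.
#' @return Matrix of physical-unit parameter rows.
#' @export
design_block <- function(design, which = c("train", "valid", "test")) {
  which <- match.arg(which)
  design$Theta[design$segment == which, , drop = FALSE]
}

#' Map physical parameter rows back to the unit cube
#' @param Theta matrix (rows are parameter vectors) or vector.
#' @param space a `pw_space`.
#' @return Same shape in `[0,1]^d`.
#' @export
to_unit_cube <- function(Theta, space) {
  if (is.null(dim(Theta))) Theta <- matrix(Theta, 1)
  sweep(sweep(Theta, 2, space$lower, `-`), 2, space$upper - space$lower, `/`)
}

#' Write a design to CSV with a JSON sidecar
#'
#' One row per point, parameter columns plus a `segment` column; bounds and
#' generator settings go to `<path>.json` for reproducibility.
#'
#' @param design a `pw_design`.
#' @param path output CSV path.
#' @param skip the skip used (recorded in the sidecar).
#' @export
write_design <- function(design, path, skip = 1) {
  df <- as.data.frame(design$Theta)
  df$segment <- as.character(design$segment)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(d = design$space$d, skip = skip,
                            names = design$space$names,
                            lower = design$space$lower,
                            upper = design$space$upper),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
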