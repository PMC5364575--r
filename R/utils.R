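# internal helpers shared across modules

stop2 <- function(...) stop(..., call. = FALSE)

assert_image <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    stop2(name, " must be a numeric matrix")
  if (anyNA(x)) stop2(name, " contains NA values")
  if (min(x) < 0) stop2(name, " must be non-negative")
  invisible(x)
}

assert_mask <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.logical(x))
    stop2(name, " must be a logical matrix")
  if (anyNA(x)) stop2(name, " contains NA values")
  invisible(x)
}

# round half away from zero (values here are always >= 0)
round_half_up <- function(x) floor(x + 0.5)

# shift a matrix by (dr, dc), padding vacated cells with `fill`
shift_matrix <- function(m, dr, dc, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  if (length(rs) && length(cs))
    out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# pad a matrix by replicating its border rows/columns k times
pad_replicate <- function(m, k) {
  h <- nrow(m); w <- ncol(m)
  ri <- c(rep(1L, k), seq_len(h), rep(h, k))
  ci <- c(rep(1L, k), seq_len(w), rep(w, k))
  m[ri, ci]
}

# run an expression with a temporary RNG seed, restoring global state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
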