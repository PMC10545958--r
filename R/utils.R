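#' @keywords internal
"_PACKAGE"

#' @importFrom stats qt rnorm runif sd cor var approx setNames dnorm
#' @importFrom utils head tail read.csv write.csv combn
NULL

# Run an expression with a locally seeded RNG, restoring global RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_param <- function(...) {
  stop(errorCondition(paste0(...), class = c("footform_parameter_error", "error")))
}

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("footform_input_error", "error")))
}

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("footform_validation_error", "error")))
}

# Rotation matrix from intrinsic XYZ Euler angles in degrees.
rotation_xyz <- function(deg) {
  r <- deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

row_norms <- function(m) sqrt(rowSums(m * m))

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
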