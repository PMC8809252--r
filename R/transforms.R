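#' Domain transforms for unconstrained variational parameters
#'
#' The variational family is a diagonal Normal in unconstrained space; each
#' latent is pushed through a fixed transform into its legal domain:
#' `positive` (elementwise exp, R -> R+), `simplex` (row-wise softmax,
#' R^K -> simplex), `unit_interval` (logistic, R -> \[0,1\]) and `identity`.
#'
#' @param name One of `"positive"`, `"simplex"`, `"unit_interval"`, `"identity"`.
#' @return A `domain_transform` with `forward`, `inverse`, and the pieces the
#'   inference engine needs: `log_jac(u, x)` (log |dT/du|, 0 for simplex where
#'   no bijective correction applies) and `backprop(g_x, u, x)` mapping the
#'   gradient wrt constrained values to the gradient of
#'   `log p(T(u)) + log|J(u)|` wrt `u`.
#' @examples
#' tr <- domain_transform("simplex")
#' rowSums(tr$forward(matrix(rnorm(6), 2)))
#' @export
domain_transform <- function(name = c("positive", "simplex", "unit_interval", "identity")) {
  name <- match.arg(name)
  t <- switch(name,
    positive = list(
      forward  = function(u) exp(u),
      inverse  = function(x) log(x),
      log_jac  = function(u, x) sum(u),
      backprop = function(g_x, u, x) g_x * x + 1
    ),
    identity = list(
      forward  = function(u) u,
      inverse  = function(x) x,
      log_jac  = function(u, x) 0,
      backprop = function(g_x, u, x) g_x
    ),
    unit_interval = list(
      forward  = function(u) stats::plogis(u),
      inverse  = function(x) stats::qlogis(x),
      log_jac  = function(u, x) sum(log(pmax(x * (1 - x), 1e-300))),
      backprop = function(g_x, u, x) g_x * x * (1 - x) + (1 - 2 * x)
    ),
    simplex = list(
      # row-wise softmax on matrices, softmax on vectors; overparameterized
      # (K unconstrained coordinates per K-simplex row), no Jacobian term
      forward = function(u) {
        if (is.matrix(u)) {
          e <- exp(u - apply(u, 1, max))
          e / rowSums(e)
        } else {
          e <- exp(u - max(u))
          e / sum(e)
        }
      },
      inverse = function(x) log(pmax(x, 1e-300)),
      log_jac = function(u, x) 0,
      backprop = function(g_x, u, x) {
        if (is.matrix(x)) {
          x * (g_x - rowSums(g_x * x))
        } else {
          x * (g_x - sum(g_x * x))
        }
      }
    )
  )
  structure(c(t, list(name = name)), class = "domain_transform")
}

#' @export
print.domain_transform <- function(x, ...) {
  cat("<domain_transform>", x$name, "\n")
  invisible(x)
}
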