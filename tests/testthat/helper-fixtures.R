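# Shared fixtures, all built in code.

# a canonical 16-point curve from values (or a function of time)
make_curve <- function(values, id = "T01", source = "plasma") {
  grid <- ogtt_grid()
  if (is.function(values)) values <- values(grid)
  glucose_curve(id, grid, values, source = source)
}

# piecewise-linear "triangle" curve: 100 at t<=0, 160 at 60, back to 100 at
# 180, sampled on the canonical grid
triangle_curve <- function() {
  make_curve(function(t) {
    ifelse(t <= 0, 100,
           ifelse(t <= 60, 100 + t, 160 - 0.5 * (t - 60)))
  })
}

# brute-force auROC: concordant-pair fraction with half credit for ties
brute_auroc <- function(scores, labels) {
  p <- scores[labels == 1]
  q <- scores[labels == 0]
  mean(outer(p, q, function(a, b) (a > b) + 0.5 * (a == b)))
}

# small linearly separable classification problem
separable_data <- function(n = 60, seed = 4) {
  withr::with_seed(seed, {
    y <- rep(c(0, 1), length.out = n)
    X <- cbind(x1 = y * 6 + rnorm(n), x2 = rnorm(n))
    list(X = X, y = y)
  })
}
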