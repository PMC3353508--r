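# shared fixtures, built in code

# noiseless leaf data on an exact power law
power_law_leaves <- function(l, a, b) {
  leaf_records(length_mm = l, weight_g = a * l^b)
}

# brute-force profile grid search for the allometric least-squares optimum:
# closed-form a(b) at each grid b, rss minimised over the grid
grid_allometric <- function(lengths_list, w, b_grid) {
  rss <- vapply(b_grid, function(b) {
    S <- vapply(lengths_list, function(l) sum(l^b), numeric(1))
    sum(w^2) - sum(w * S)^2 / sum(S^2)
  }, numeric(1))
  i <- which.min(rss)
  S <- vapply(lengths_list, function(l) sum(l^b_grid[i]), numeric(1))
  list(a = sum(w * S) / sum(S^2), b = b_grid[i], rss = rss[i])
}

# grid maximisation of |theta| over (0, l_star)
grid_theta_max <- function(a, b, c, n_grid = 1e6) {
  l_star <- threshold_length(a, b, c)
  l <- seq(l_star / n_grid, l_star, length.out = n_grid)
  max(abs(c * l - a * l^b))
}

# random positive (a, b, c) triples with b bounded away from 1
random_triples <- function(n, seed) {
  set.seed(seed)
  data.frame(
    a = 10^runif(n, -6, -3),
    b = sample(c(runif(ceiling(n / 2), 1.05, 1.8),
                 runif(floor(n / 2), 0.4, 0.95))),
    c = 10^runif(n, -5, -3))
}
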