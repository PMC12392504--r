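# shared fixture builders (all generated in code; no stored data)

# logistic disk phase field with half-level at radius R (um)
make_disk <- function(R, params = model_params(), L = 3 * R, center = c(0, 0),
                      dx = params$dx) {
  n <- round(2 * L / dx) + 1
  org <- c(-L, -L)
  xs <- org[1] + (seq_len(n) - 1) * dx
  r <- sqrt(outer((xs - center[1])^2, (xs - center[2])^2, "+"))
  k <- sqrt(2 * params$c0) / params$lambda
  scalar_field(1 / (1 + exp(k * (r - R))), dx, org)
}

# sharp indicator disk (phi = 1 inside radius R)
make_sharp_disk <- function(R, dx = 1, L = 2 * R) {
  n <- round(2 * L / dx) + 1
  org <- c(-L, -L)
  xs <- org[1] + (seq_len(n) - 1) * dx
  r <- sqrt(outer((xs)^2, (xs)^2, "+"))
  scalar_field(matrix(as.numeric(r <= R), n, n), dx, org)
}

const_field <- function(value, like) {
  scalar_field(matrix(value, nrow(like$values), ncol(like$values)),
               like$dx, like$origin)
}

# minimal trajectory wrapper for inference/observable tests
fake_traj2 <- function(t, x) {
  tr <- data.frame(t_min = t, x_um = x, y_um = 0,
                   area_um2 = NA_real_, perim_um = NA_real_)
  class(tr) <- c("pf_trajectory", "data.frame")
  tr
}
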