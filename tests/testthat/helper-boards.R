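# Shared fixtures: random valid curves and small noiseless boards built in
# code at test time.

random_curve <- function(b = NULL) {
  if (is.null(b)) b <- runif(1, -0.5, 0.5)
  marginal_curve(b = b,
                 m = b + sample(c(-1, 1), 1) * runif(1, 0.2, 1.5),
                 ec50 = 10^runif(1, -1.5, 1.5),
                 hill = runif(1, 0.5, 4))
}

random_curve_pair <- function() {
  b <- runif(1, -0.5, 0.5)
  list(random_curve(b), random_curve(b))
}

# Noiseless mono-therapy board on an 8-point 2-fold dilution series per
# compound (7 nonzero doses + dose 0), readouts exactly on the curves.
noiseless_board <- function(curves,
                            doses1 = curves[[1]]$ec50 * 2^(-3:3),
                            doses2 = curves[[2]]$ec50 * 2^(-3:3)) {
  data.frame(
    d1 = c(0, doses1, rep(0, length(doses2))),
    d2 = c(0, rep(0, length(doses1)), doses2),
    effect = c(curves[[1]]$b,
               readout(curves[[1]], doses1),
               readout(curves[[2]], doses2)))
}

default_true_theta <- c(b = 0.1, m1 = 1, m2 = 0.6, li1 = 0, li2 = log(10),
                        h1 = 1, h2 = 2)

scratch_path <- function(name) tempfile(fileext = paste0("-", name))
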