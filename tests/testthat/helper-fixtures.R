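# shared fixtures: bench-scale system, a unit calibration, and a brute-force
# bisection solver used as the independent oracle for the batch equilibrium

bench_system <- function() batch_system(0.0045, 10, 6.75)

unit_calibration <- function() {
  assay_calibration(slope = 0.001, intercept = 0, dilution_factor = 1,
                    background_scale = 1)
}

# independent oracle: bisection on the mass-balance residual in C
bisect_batch_c <- function(V, m, total, K, S, tol = 1e-13) {
  f <- function(C) C * V + m * K * C * S / (1 + K * C) - total
  lo <- 0
  hi <- total / V
  if (f(hi) < 0) return(hi)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if ((hi - lo) < tol * max(hi, 1)) break
  }
  (lo + hi) / 2
}

random_batch_instance <- function() {
  list(V = stats::runif(1, 1e-3, 10),
       m = stats::runif(1, 0.1, 1e4),
       total = stats::runif(1, 0.1, 5e3),
       K = 10^stats::runif(1, -4, 2),
       S = stats::runif(1, 1e-3, 1))
}
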