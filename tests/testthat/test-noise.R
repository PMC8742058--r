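random_density <- function(n) {
  # mixture of a few random pure states
  N <- 2^n
  rho <- matrix(0i, N, N)
  w <- stats::runif(3)
  w <- w / sum(w)
  for (j in 1:3) {
    v <- complex(real = stats::rnorm(N), imaginary = stats::rnorm(N))
    v <- v / sqrt(sum(Mod(v)^2))
    rho <- rho + w[j] * (v %o% Conj(v))
  }
  rho
}

test_that("the depolarizing channel mixes toward identity and preserves trace", {
  rho <- density_from_state(basis_state(1))
  expect_equal(depolarizing_channel(rho, 0, 0L), rho)

  # p = 1 replaces the qubit by the completely mixed state
  out <- depolarizing_channel(rho, 1, 0L)
  expect_equal(out, matrix(c(0.5, 0, 0, 0.5), 2, 2) + 0i, tolerance = 1e-12)

  set.seed(61)
  for (trial in 1:100) {
    n <- sample(1:3, 1)
    rho <- random_density(n)
    p <- stats::runif(1)
    qs <- sample(0:(n - 1L), sample(1:min(2, n), 1))
    out <- depolarizing_channel(rho, p, qs)
    expect_equal(Re(sum(diag(out))), 1, tolerance = 1e-9)
    expect_lt(max(Mod(out - Conj(t(out)))), 1e-9)
    expect_gte(min(Re(eigen(out, only.values = TRUE)$values)), -1e-9)
  }
})

test_that("thermal relaxation damps populations and coherences as prescribed", {
  plus <- apply_gate(basis_state(1), gate_h(0))
  rho <- density_from_state(plus)

  expect_equal(thermal_relaxation_channel(rho, 50, 70, 0), rho)

  # infinite duration relaxes to |0>
  out <- thermal_relaxation_channel(density_from_state(basis_state(1, 1)),
                                    50, 70, 1e9)
  expect_equal(Re(out[1, 1]), 1, tolerance = 1e-6)

  # at t = T2 the off-diagonal of |+> shrinks to exp(-1)/2
  out <- thermal_relaxation_channel(rho, t1 = 100, t2 = 80, duration = 80)
  expect_equal(Mod(out[1, 2]), exp(-1) / 2, tolerance = 1e-9)

  expect_error(thermal_relaxation_channel(rho, 10, 30, 5), "unphysical")
  expect_error(noise_model(t1 = 10, t2 = 30), "unphysical")
})

test_that("readout error mixes outcome bits and conserves probability", {
  p <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(apply_readout_error(p, diag(2)), p)

  flipall <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(apply_readout_error(p, flipall), rev(p))

  set.seed(67)
  for (trial in 1:20) {
    p <- stats::runif(8); p <- p / sum(p)
    e01 <- stats::runif(1, 0, 0.2); e10 <- stats::runif(1, 0, 0.2)
    M <- matrix(c(1 - e01, e01, e10, 1 - e10), 2, 2, byrow = TRUE)
    out <- apply_readout_error(p, M)
    expect_equal(sum(out), 1, tolerance = 1e-12)
    expect_true(all(out >= 0))
  }
  expect_error(apply_readout_error(p, matrix(c(0.5, 0.4, 0.1, 0.9), 2, 2)),
               "row-stochastic")
})

test_that("noiseless density-matrix simulation reproduces the ideal distribution", {
  circ <- decompose_circuit(qpatent:::fig1f_grover_circuit())
  out <- simulate_noisy(circ, noise_model(), shots = 512, seed = 10)
  expect_equal(out$probabilities, c(1, 0, 0, 0), tolerance = 1e-9)
  expect_equal(sum(out$counts), 512L)

  out2 <- simulate_noisy(circ, noise_model(), shots = 512, seed = 10)
  expect_identical(out$counts, out2$counts)
})

test_that("any depolarizing noise strictly lowers the correct-state probability", {
  circ <- decompose_circuit(qpatent:::fig1f_grover_circuit())
  noisy <- simulate_noisy(circ, noise_model(p_depol_1q = 0.002,
                                            p_depol_2q = 0.02),
                          shots = 256, seed = 11)
  expect_lt(noisy$probabilities[1], 1)
  expect_gt(noisy$probabilities[1], 0.25) # still the dominant outcome
})

test_that("correctness is monotone non-increasing in each error family's scale", {
  circ <- decompose_circuit(qpatent:::fig1f_grover_circuit())
  nm <- default_noise_model()
  for (fam in c("thermal", "depolarizing", "readout")) {
    df <- error_scaling_experiment(circ, nm, fam, correct_states = "00",
                                   shots = 1024, repeats = 10, seed = 21)
    expect_equal(df$factor, c(0.5, 1, 2))
    expect_true(all(diff(df$mean_correct) < 0), info = fam)
    expect_true(all(df$ci_lo <= df$mean_correct & df$mean_correct <= df$ci_hi))
  }
  expect_error(error_scaling_experiment(circ, nm, "cosmic", "00"),
               "unknown error family")
})

test_that("zero base noise yields full correctness at every scale factor", {
  circ <- decompose_circuit(qpatent:::fig1f_grover_circuit())
  df <- error_scaling_experiment(circ, noise_model(), "depolarizing",
                                 correct_states = "00", shots = 256,
                                 repeats = 3, seed = 31)
  expect_equal(df$mean_correct, rep(1, 3))
})

test_that("halving depolarizing noise helps most when it dominates", {
  circ <- decompose_circuit(qpatent:::fig1f_grover_circuit())
  nm <- default_noise_model() # per-gate depolarizing dominates by design
  gain <- vapply(c("thermal", "depolarizing", "readout"), function(fam) {
    df <- error_scaling_experiment(circ, nm, fam, correct_states = "00",
                                   shots = 1024, repeats = 5, seed = 41)
    df$mean_correct[df$factor == 0.5] - df$mean_correct[df$factor == 1]
  }, numeric(1))
  expect_equal(names(which.max(gain)), "depolarizing")
})

test_that("noise configs round trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("t1: 50000", "t2: 70000", "p_depol_1q: 0.001",
               "p_depol_2q: 0.01",
               "gate_durations: {1q: 50, cnot: 300}",
               "readout: [0.98, 0.02, 0.03, 0.97]"), path)
  nm <- read_noise_model(path)
  expect_equal(nm$t1, 50000)
  expect_equal(nm$readout[2, 1], 0.03)
})
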