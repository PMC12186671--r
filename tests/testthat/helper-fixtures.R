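# shared builders for tests: small deterministic ground truths, contexts and
# a reference fixed-step RK4 integrator written directly from the model
# equations (kept independent of the package's adaptive solver)

test_context <- function() {
  c(medium = "M0", supplement = "S0", promoter = "P1", rbs = "R1")
}

test_gt <- function(seed = 42) draw_ground_truth(seed = seed)

test_gp <- function() growth_params(L1 = 1.1, a1 = 0.6, t1 = 6,
                                    k1 = 0.2, k2 = 1.3)

test_kp <- function(...) {
  args <- list(vmax_PROM = 0.5, K_Pk = 1, K_mRNAp = 1, k_deg = 0.3,
               K_mRNAdeg = 1, K_P = 1, K_lysis = 1, RBS_strength = 1.5,
               k_FDER = 1.2, K_NFDER = 1, k_deg_FDER = 0.1, vmax_NAR = 2,
               k_deg_GFP = 0.1, R_basal = 0.3)
  args[names(list(...))] <- list(...)
  do.call(kinetic_params, args)
}

# independent fixed-step classical RK4 solution of the reporter equations,
# transcribed from the model definition (not from the package's solver)
rk4_reference <- function(gp, kp, times, init = c(0, 0, 0), refine = 100,
                          frozen = FALSE) {
  mu_fun <- function(t) {
    if (frozen) return(0)
    s1 <- plogis(gp$a1 * (t - gp$t1))
    s2 <- plogis((gp$k1 * gp$a1) * (t - gp$k2 * gp$t1))
    n <- gp$L1 * s1 + gp$k1 * s2
    dn <- gp$L1 * gp$a1 * s1 * (1 - s1) +
      gp$k1 * (gp$k1 * gp$a1) * s2 * (1 - s2)
    dn / n
  }
  tt_fine <- seq(0, max(times), by = 0.01)
  mu_max <- if (frozen) 0 else max(vapply(tt_fine, mu_fun, numeric(1)))
  f <- function(t, y) {
    mu <- mu_fun(t)
    A <- if (mu_max > 0) min(max(mu / mu_max, 0), 1) else 0
    R <- A + kp$R_basal * (1 - A)
    fh <- y[2]^kp$hill_exp
    c(kp$vmax_PROM * kp$K_Pk * kp$K_mRNAp - mu * y[1] -
        kp$k_deg * kp$K_mRNAdeg * y[1],
      kp$k_FDER * R * kp$RBS_strength * y[1] / (y[1] + kp$K_NFDER) -
        kp$k_deg_FDER * y[2] * kp$K_lysis - mu * y[2],
      kp$vmax_NAR * kp$K_P * R * fh / (fh + kp$hill_half^kp$hill_exp) -
        kp$k_deg_GFP * y[3] * kp$K_lysis - mu * y[3])
  }
  out <- matrix(NA_real_, length(times), 3)
  out[1, ] <- y <- init
  for (i in 2:length(times)) {
    h <- (times[i] - times[i - 1]) / refine
    t <- times[i - 1]
    for (s in seq_len(refine)) {
      k1_ <- f(t, y)
      k2_ <- f(t + h / 2, y + h / 2 * k1_)
      k3_ <- f(t + h / 2, y + h / 2 * k2_)
      k4_ <- f(t + h, y + h * k3_)
      y <- y + h / 6 * (k1_ + 2 * k2_ + 2 * k3_ + k4_)
      t <- t + h
    }
    out[i, ] <- y
  }
  out
}

# brute-force one-tailed Kendall p by direct permutation enumeration,
# written independently of the package implementation
brute_kendall_p <- function(x, y) {
  n <- length(x)
  s_of <- function(xx, yy) {
    s <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      s <- s + sign(xx[j] - xx[i]) * sign(yy[j] - yy[i])
    s
  }
  s_obs <- s_of(x, y)
  perms <- NULL
  gen <- function(v, acc) {
    if (length(v) == 0) { perms[[length(perms) + 1]] <<- acc; return() }
    for (i in seq_along(v)) gen(v[-i], c(acc, v[i]))
  }
  gen(seq_len(n), integer(0))
  cnt <- sum(vapply(perms, function(p) s_of(x, y[p]) >= s_obs - 1e-9,
                    logical(1)))
  cnt / length(perms)
}

# apply scoped free-parameter values (e.g. "RBS_strength.M0_S0_P1_R1") to a
# kinetic parameter set
update_kp <- function(kp, named_scoped) {
  for (nm in names(named_scoped)) {
    base <- strsplit(nm, ".", fixed = TRUE)[[1]][1]
    kp[[base]] <- unname(named_scoped[[nm]])
  }
  do.call(kinetic_params, unclass(kp))
}
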