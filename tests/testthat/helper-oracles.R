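# Independent oracles used to cross-check the implementation. Each is a
# deliberately different route to the same quantity: regex matching for the
# window scanner, bisection on mass balance for the binding quadratic, a
# numerical ODE solve for the closed-form biosensor traces, and brute-force
# fine grids for interpolated quantities.

# Character-by-character regular-expression oracle for scan_sequence:
# builds one character class per window position and counts overlapping
# matches with a lookahead.
regex_scan_count <- function(template, sequence) {
  n <- template$length
  classes <- vapply(seq_len(n), function(pos) {
    if (pos %in% template$buried) {
      paste0("[", paste(BURIED_ALLOWED, collapse = ""), "]")
    } else if (pos == 1L || pos == n) {
      "."
    } else {
      "[^P]"
    }
  }, character(1))
  pat <- paste0("(?=", paste(classes, collapse = ""), ")")
  m <- gregexpr(pat, sequence, perl = TRUE)[[1L]]
  if (length(m) == 1L && m[1L] == -1L) 0L else length(m)
}

# Per-window brute-force checker, position by position in a plain loop.
brute_scan_starts <- function(template, sequence) {
  n <- template$length
  L <- nchar(sequence)
  if (L < n) return(integer())
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  hits <- integer()
  for (s in seq_len(L - n + 1L)) {
    ok <- TRUE
    for (pos in seq_len(n)) {
      ch <- chars[s + pos - 1L]
      if (pos %in% template$buried) {
        if (!(ch %in% BURIED_ALLOWED)) { ok <- FALSE; break }
      } else if (pos != 1L && pos != n && ch == "P") {
        ok <- FALSE; break
      }
    }
    if (ok) hits <- c(hits, s)
  }
  hits
}

random_template <- function() {
  n <- sample(4:12, 1L)
  burial_template("rnd", n, sample.int(n, sample.int(n, 1L)))
}

random_sequence <- function() {
  paste(sample(AA_CANONICAL, sample(20:200, 1L), replace = TRUE),
        collapse = "")
}

# Bisection oracle on the 1:1 mass balance: find complex concentration C
# such that (L - C)(B - C) = Kd * C.
bisect_complex <- function(Ltot, Btot, Kd, tol = 1e-18) {
  f <- function(C) (Ltot - C) * (Btot - C) - Kd * C
  lo <- 0
  hi <- min(Ltot, Btot)
  if (hi == 0) return(0)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# Numerical ODE oracle for the 1:1 biosensor model.
ode_binding_trace <- function(t, C, kon, koff, Rmax, R0 = 0) {
  sol <- deSolve::lsoda(
    y = c(R = R0), times = t,
    func = function(tt, y, p) list(kon * C * (Rmax - y[1L]) - koff * y[1L]),
    parms = NULL, rtol = 1e-10, atol = 1e-12
  )
  sol[, "R"]
}

# Fine-grid half-time oracle: crossing of half the final plateau located on
# a 100x refined linear interpolation of the trajectory.
fine_grid_half_time <- function(traj) {
  tt <- seq(min(traj$t), max(traj$t), length.out = length(traj$t) * 100L)
  MM <- stats::approx(traj$t, traj$M, xout = tt)$y
  target <- 0.5 * MM[length(MM)]
  i <- which(MM >= target)[1L]
  tt[i]
}
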