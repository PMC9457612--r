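# Independent numerical oracles and small shared fixtures.

# worst per-step relative change of a conserved total; a component whose
# scale is at round-off is conserved by definition
max_rel_step_drift <- function(tot) {
  s <- max(abs(tot))
  if (s < 1e-12) return(0)
  max(abs(diff(tot))) / s
}

# brute-force 5-point Laplacian with ghost-cell reflection (no-flux)
lap_stencil_oracle <- function(u, h) {
  up <- rbind(u[1, ], u[-nrow(u), ])
  dn <- rbind(u[-1, ], u[nrow(u), ])
  lf <- cbind(u[, 1], u[, -ncol(u)])
  rt <- cbind(u[, -1], u[, ncol(u)])
  (up + dn + lf + rt - 4 * u) / h^2
}

# 4-neighbour connected-component count of a logical matrix (flood fill)
n_connected_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  for (i0 in seq_len(nrow(mask))) for (j0 in seq_len(ncol(mask))) {
    if (!mask[i0, j0] || lab[i0, j0] > 0L) next
    nxt <- nxt + 1L
    queue <- list(c(i0, j0))
    lab[i0, j0] <- nxt
    while (length(queue)) {
      p <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        q <- p + d
        if (q[1] < 1 || q[2] < 1 || q[1] > nrow(mask) || q[2] > ncol(mask)) next
        if (mask[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
          lab[q[1], q[2]] <- nxt
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
  }
  nxt
}

# overrides for a fast, small destruction-complex scenario
tiny_dc_overrides <- function(nx = 24, n_steps = 10) {
  list(grid = list(nx = nx, ny = nx, lx = 1, ly = 1),
       solver = list(n_steps = n_steps, snapshot_every = n_steps))
}

# mean-field ODE solution of the two-step cascade at constant catalysts
cascade_ode_oracle <- function(k1, k2, phi_ck1, phi_gsk3, bcat0, t_end) {
  f <- function(t, y, p) {
    list(c(-k1 * phi_ck1 * y[1],
           k1 * phi_ck1 * y[1] - k2 * phi_gsk3 * y[2],
           k2 * phi_gsk3 * y[2]))
  }
  out <- deSolve::lsoda(c(bcat = bcat0, p1 = 0, p4 = 0),
                        times = c(0, t_end), f, NULL,
                        rtol = 1e-12, atol = 1e-16)
  out[2, 2:4]
}

# lazily computed shared runs for the expensive acceptance checks
.acc_cache <- new.env(parent = emptyenv())
acc_get <- function(name, fun) {
  if (!exists(name, envir = .acc_cache, inherits = FALSE)) {
    assign(name, fun(), envir = .acc_cache)
  }
  get(name, envir = .acc_cache, inherits = FALSE)
}

default_dc_pair_100 <- function() {
  acc_get("dc_pair_100", function() {
    pair <- gen_dc_scenario(seed = 1)
    list(pair = pair,
         nucleated = run_sim(pair$nucleated),
         free = run_sim(pair$free))
  })
}

default_dc_k0_100 <- function() {
  acc_get("dc_k0_100", function() {
    pair <- gen_dc_scenario(overrides = list(rates = NULL), seed = 1)
    run_sim(pair$nucleated)
  })
}
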