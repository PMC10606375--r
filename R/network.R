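# Generic compartment-network machinery.
#
# A network is a component table (name, group, volume, is_mass) plus a link
# table (from, to, psa = permeability * area, kp). Every link contributes the
# flux f = psa * (C_from - C_to / kp) (kg/s), which is removed from `from` and
# added to `to`; this antisymmetric bookkeeping conserves mass by
# construction. Links are linear in the state, so the whole linear part is
# pre-assembled into one dense amount-operator matrix; only particle
# dissolution is nonlinear and handled as an additive term.

# amount-derivative operator: damt = amat %*% state
network_operator <- function(comps, links) {
  n <- nrow(comps)
  amat <- matrix(0, n, n)
  if (!is.null(links) && nrow(links) > 0) {
    for (l in seq_len(nrow(links))) {
      i <- links$from[l]; j <- links$to[l]
      psa <- links$psa[l]; kp <- links$kp[l]
      amat[i, i] <- amat[i, i] - psa
      amat[i, j] <- amat[i, j] + psa / kp
      amat[j, i] <- amat[j, i] + psa
      amat[j, j] <- amat[j, j] - psa / kp
    }
  }
  inv_vol <- ifelse(comps$is_mass, 1, 1 / comps$volume)
  list(amat = amat, inv_vol = inv_vol)
}

MIN_PARTICLE_RADIUS <- 1e-9  # m; dissolution radius guard

# additive RHS of Nernst-Brunner dissolution for all solid states
solids_rhs <- function(solids, state, inv_vol) {
  dy <- numeric(length(state))
  s <- pmax(state[solids$solid], 0)
  cv <- state[solids$liquid]
  active <- s > 0 & solids$np > 0
  if (any(solids$shrinking)) {
    r <- ifelse(active,
                (3 * s / (4 * pi * solids$rho * pmax(solids$np, 1)))^(1 / 3),
                0)
  } else {
    r <- rep(solids$r0, length.out = length(s))
  }
  r <- pmax(r, MIN_PARTICLE_RADIUS)
  sa_tot <- 3 * s / (solids$rho * r)          # = np * 4 pi r^2 (mass-consistent)
  flux <- solids$dp * sa_tot * (solids$cs - cv) / r
  flux[!active] <- 0                           # exhausted: no exchange
  dy[solids$solid] <- -flux
  dy[solids$liquid] <- dy[solids$liquid] + flux * inv_vol[solids$liquid]
  dy
}

# Jacobian contribution of the dissolution terms (dense, in state units)
solids_jac <- function(solids, state, inv_vol, jac) {
  s <- pmax(state[solids$solid], 0)
  cv <- state[solids$liquid]
  active <- s > 0 & solids$np > 0
  if (any(solids$shrinking)) {
    r_raw <- ifelse(active,
                    (3 * s / (4 * pi * solids$rho *
                                pmax(solids$np, 1)))^(1 / 3),
                    0)
  } else {
    r_raw <- rep(solids$r0, length.out = length(s))
  }
  clamped <- r_raw <= MIN_PARTICLE_RADIUS
  r <- pmax(r_raw, MIN_PARTICLE_RADIUS)
  sa_over_s <- 3 / (solids$rho * r)            # sa_tot = s * sa_over_s
  flux_per_s <- solids$dp * sa_over_s * (solids$cs - cv) / r
  # d flux / d s: flux ~ s^(1/3) (shrinking, unclamped) or ~ s (clamped/fixed)
  dfds <- ifelse(solids$shrinking & !clamped, flux_per_s / 3, flux_per_s)
  dfds[!active] <- 0
  dfdc <- -solids$dp * (s * sa_over_s) / r
  dfdc[!active] <- 0
  for (k in seq_len(nrow(solids))) {
    si <- solids$solid[k]; li <- solids$liquid[k]
    jac[si, si] <- jac[si, si] - dfds[k]
    jac[si, li] <- jac[si, li] - dfdc[k]
    jac[li, si] <- jac[li, si] + dfds[k] * inv_vol[li]
    jac[li, li] <- jac[li, li] + dfdc[k] * inv_vol[li]
  }
  jac
}

# Steady state of the linear network with some components pinned (Dirichlet).
# Returns the full concentration vector. `pinned` is a named-by-index vector.
network_steady_state <- function(comps, links, pinned) {
  op <- network_operator(comps, links)
  a <- op$amat
  n <- nrow(comps)
  free <- setdiff(seq_len(n), as.integer(names(pinned)))
  conc <- numeric(n)
  conc[as.integer(names(pinned))] <- pinned
  if (length(free) > 0) {
    aff <- a[free, free, drop = FALSE]
    rhs <- -a[free, as.integer(names(pinned)), drop = FALSE] %*% pinned
    qr_a <- qr(aff)
    if (qr_a$rank < length(free)) {
      stop("flux network is singular (disconnected components)", call. = FALSE)
    }
    conc[free] <- solve(qr_a, rhs)
  }
  conc
}

# total flux (kg/s) leaving a set of source components toward the rest
network_boundary_flux <- function(links, conc, sources) {
  f <- 0
  src <- links$from %in% sources & !(links$to %in% sources)
  if (any(src)) {
    f <- f + sum(links$psa[src] *
                   (conc[links$from[src]] - conc[links$to[src]] / links$kp[src]))
  }
  rev <- links$to %in% sources & !(links$from %in% sources)
  if (any(rev)) {
    f <- f - sum(links$psa[rev] *
                   (conc[links$from[rev]] - conc[links$to[rev]] / links$kp[rev]))
  }
  f
}
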