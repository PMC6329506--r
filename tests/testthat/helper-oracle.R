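# Independent brute-force reference simulator for the competitive
# radius-expanding greedy allocation. Deliberately naive: every turn rescans
# the whole grid for the settlement's best available pixel. Used to verify
# the package engine pixel-for-pixel on small instances.

oracle_allocate <- function(energy_px, cell, xll, yll, sett, demands,
                            radii_m, offtake) {
  nr <- nrow(energy_px); nc <- ncol(energy_px)
  cx <- matrix(rep(xll + (seq_len(nc) - 0.5) * cell, each = nr), nr, nc)
  cy <- matrix(rep(yll + (nr - seq_len(nr) + 0.5) * cell, times = nc), nr, nc)
  claim <- matrix(0L, nr, nc); grp <- matrix(0L, nr, nc)
  cons <- matrix(0, nr, nc)
  ns <- nrow(sett); ng <- length(radii_m)
  met <- matrix(FALSE, ns, ng); maxd <- matrix(0, ns, ng)
  npix <- matrix(0L, ns, ng)
  d2 <- lapply(seq_len(ns),
               function(s) (cx - sett$x[s])^2 + (cy - sett$y[s])^2)
  maxfeas2 <- vapply(d2, max, numeric(1))
  rm_index <- (row(energy_px) - 1L) * nc + col(energy_px)  # row-major order
  for (g in seq_len(ng)) {
    rem <- demands[, g]
    active <- rem > 0
    met[, g] <- !active
    k <- 0
    while (any(active)) {
      k <- k + 1
      R2 <- (k * radii_m[g])^2
      repeat {
        claimed_any <- FALSE
        for (s in which(active)) {
          cand <- which(claim == 0L & energy_px > 0 & d2[[s]] <= R2)
          if (length(cand) == 0) {
            if (R2 >= maxfeas2[s]) active[s] <- FALSE
            next
          }
          best <- cand[order(-energy_px[cand], d2[[s]][cand],
                             rm_index[cand])[1]]
          claim[best] <- s; grp[best] <- g
          take <- min(offtake[s] * energy_px[best], rem[s])
          cons[best] <- take
          rem[s] <- rem[s] - take
          npix[s, g] <- npix[s, g] + 1L
          maxd[s, g] <- max(maxd[s, g], sqrt(d2[[s]][best]))
          claimed_any <- TRUE
          if (rem[s] <= 0) { active[s] <- FALSE; met[s, g] <- TRUE }
        }
        if (!claimed_any) break
      }
    }
  }
  list(claim = claim, group = grp, consumed = cons, met = met,
       max_d_m = maxd, n_pixels = npix)
}
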