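# Independent brute-force implementations used as oracles, plus cached
# mimetic builds shared across test files.

.build_cache <- new.env(parent = emptyenv())
cached_mimetic <- function(residue, backbone_angle = 110) {
  key <- paste(residue, backbone_angle)
  if (is.null(.build_cache[[key]])) {
    .build_cache[[key]] <- build_mimetic(residue, backbone_angle)
  }
  .build_cache[[key]]
}

# breadth-first-search shortest path in a bond graph (edge list matrix)
bfs_separation <- function(bonds, n, from, to) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    a <- bonds[r, 1L]; b <- bonds[r, 2L]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  dist <- rep(NA_integer_, n)
  dist[from] <- 0L
  queue <- from
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]) {
      if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        queue <- c(queue, w)
      }
    }
  }
  dist[to]
}

# naive O(n^2) overlap counter over all eligible pairs
naive_overlaps <- function(st, radii, min_sep = 4L) {
  n <- nrow(st$atoms)
  count <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (st$sep[i, j] >= min_sep) {
        d <- sqrt(sum((st$xyz[i, ] - st$xyz[j, ])^2))
        rs <- radii[st$atoms$element[i], st$atoms$element[j]]
        if (d < rs) count <- count + 1L
      }
    }
  }
  count
}

naive_lj_energy <- function(st, params, min_sep = 4L) {
  n <- nrow(st$atoms)
  total <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (st$sep[i, j] >= min_sep) {
        d <- sqrt(sum((st$xyz[i, ] - st$xyz[j, ])^2))
        total <- total + lj_pair_energy(d, st$atoms$element[i],
                                        st$atoms$element[j], params)
      }
    }
  }
  total
}

naive_admissible <- function(st, radii, lambda, min_sep = 4L) {
  n <- nrow(st$atoms)
  bb <- st$atoms$role %in% c("backbone", "cap")
  sc <- st$atoms$role == "sidechain"
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (st$sep[i, j] >= min_sep &&
          ((bb[i] && sc[j]) || (sc[i] && bb[j]))) {
        d <- sqrt(sum((st$xyz[i, ] - st$xyz[j, ])^2))
        rs <- radii[st$atoms$element[i], st$atoms$element[j]]
        if (d <= lambda * rs) return(FALSE)
      }
    }
  }
  TRUE
}

# brute-force scans that rebuild the structure with set_torsion for every
# configuration -- no incremental rotation, no pair decomposition
naive_scans <- function(st, radii, params, lambdas, backbone_step, chi_step,
                        penalty = 5e5, outermost_first = TRUE) {
  centers <- bin_centers(backbone_step)
  chis <- setdiff(names(st$torsions), c("phi", "psi"))
  if (!outermost_first) chis <- rev(chis)
  chi0 <- vapply(chis, function(ch) get_torsion(st, ch), numeric(1))
  deltas <- seq(0, 360 - chi_step, by = chi_step)
  nb <- length(centers)
  ov <- matrix(0, nb, nb)
  ljg <- lapply(lambdas, function(l) matrix(0, nb, nb))
  cfgs <- if (length(chis) == 0L) matrix(0, 1, 0) else
    as.matrix(expand.grid(rep(list(deltas), length(chis))))
  for (ip in seq_len(nb)) {
    for (is in seq_len(nb)) {
      s1 <- set_torsion(set_torsion(st, "phi", centers[ip]),
                        "psi", centers[is])
      tot <- 0; ev <- numeric(0)
      adm <- matrix(NA, nrow(cfgs), length(lambdas))
      for (r in seq_len(nrow(cfgs))) {
        s2 <- s1
        for (ci in seq_along(chis)) {
          s2 <- set_torsion(s2, chis[ci], chi0[ci] + cfgs[r, ci])
        }
        tot <- tot + naive_overlaps(s2, radii)
        ev <- c(ev, naive_lj_energy(s2, params))
        for (q in seq_along(lambdas)) {
          adm[r, q] <- naive_admissible(s2, radii, lambdas[q])
        }
      }
      ov[ip, is] <- tot / nrow(cfgs)
      for (q in seq_along(lambdas)) {
        ljg[[q]][ip, is] <- if (any(adm[, q])) mean(ev[adm[, q]]) else penalty
      }
    }
  }
  list(overlap = ov, lj = ljg)
}

# direct quadrature of a Karplus curve against a 1D distribution,
# evaluated by interpolating the distribution onto a 0.1-degree grid
karplus_quadrature <- function(P1d, A, B, C, offset) {
  J_of <- function(th) {
    ct <- cos((th + offset) * pi / 180)
    A * ct^2 + B * ct + C
  }
  sum(P1d$prob * J_of(P1d$theta))
}
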