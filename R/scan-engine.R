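# Shared scan engine for the average-overlap and mean-field Lennard-Jones
# landscapes.
#
# For every (phi, psi) bin the full nested product of side-chain torsion
# configurations is enumerated.  Instead of rebuilding coordinates per
# configuration, eligible atom pairs are split by which torsions move them
# relative to each other (chi2 is a nested subset of chi1's rotating set):
#
#   class "fix" : both atoms co-rotate -> distance fixed per bin
#   class "c1"  : distance depends on chi1 only
#   class "c2"  : distance depends on chi2 only (both atoms inside chi1's
#                 rotating set, so their relative geometry ignores chi1)
#   class "c12" : backbone/cap atom vs inner side-chain atom -> both angles
#
# Rigid-rotation positions for all angles of a sweep are generated at once
# (rotate_positions_multi), and the c12 block reduces to one matrix product
# per static atom.  The decomposition is exact; the brute-force
# per-configuration rebuild is kept as a test oracle.  Admissibility for
# any number of lambda values comes from one pass: the minimum of
# d^2 / R_s^2 over backbone--side-chain pairs is tracked per configuration
# and later compared against lambda^2.  Supports 0-2 chi torsions, which
# covers ALA/VAL/LEU/ILE.

chi_scan_engine <- function(structure, radii = NULL, params = NULL,
                            lambdas = numeric(0),
                            backbone_step = 2, chi_step = 2,
                            compute = c("overlap", "lj"),
                            penalty = 5e5) {
  compute <- match.arg(compute, several.ok = TRUE)
  do_ov <- "overlap" %in% compute
  do_lj <- "lj" %in% compute
  if (360 %% backbone_step != 0 || 360 %% chi_step != 0) {
    stop("scan steps must divide 360", call. = FALSE)
  }
  if (do_lj && (is.null(params) || length(lambdas) == 0L)) {
    stop("LJ scan needs `params` and at least one lambda", call. = FALSE)
  }

  chis <- setdiff(names(structure$torsions), c("phi", "psi"))
  nchi <- length(chis)
  if (nchi > 2L) stop("engine supports at most two chi torsions",
                      call. = FALSE)

  mask <- pair_mask(structure, "all")
  rs2 <- radii_lookup(radii, mask$elem_i, mask$elem_j)^2
  if (do_lj) {
    pp <- lj_combine(params, mask$elem_i, mask$elem_j)
    eps <- pp$epsilon; rmin <- pp$rmin
  } else {
    eps <- rmin <- rep(0, nrow(mask))
  }
  role <- structure$atoms$role
  bbsc <- (role[mask$i] %in% c("backbone", "cap") & role[mask$j] == "sidechain") |
          (role[mask$j] %in% c("backbone", "cap") & role[mask$i] == "sidechain")

  lvl <- integer(nrow(structure$atoms))
  if (nchi >= 1L) lvl[structure$torsions[[chis[1L]]]$rotating] <- 1L
  if (nchi == 2L) lvl[structure$torsions[[chis[2L]]]$rotating] <- 2L

  li <- lvl[mask$i]; lj <- lvl[mask$j]
  lo <- pmin(li, lj); hi <- pmax(li, lj)
  cls <- ifelse(lo == hi, "fix",
         ifelse(lo == 0L & hi == 1L, "c1",
         ifelse(lo == 1L & hi == 2L, "c2", "c12")))

  class_info <- function(cl) {
    r <- which(cls == cl)
    if (cl == "fix") {
      return(list(rows = r, i = mask$i[r], j = mask$j[r]))
    }
    sw <- lvl[mask$i[r]] > lvl[mask$j[r]]
    stat <- ifelse(sw, mask$j[r], mask$i[r])
    mov <- ifelse(sw, mask$i[r], mask$j[r])
    um <- sort(unique(mov)); us <- sort(unique(stat))
    list(rows = r, stat = stat, mov = mov, ustat = us, umov = um,
         map_s = match(stat, us), map_m = match(mov, um))
  }
  info <- lapply(c("fix", "c1", "c2", "c12"), class_info)
  names(info) <- c("fix", "c1", "c2", "c12")
  # c12 rows grouped by static atom: one matrix product per static atom
  c12_groups <- if (length(info$c12$rows)) {
    split(seq_along(info$c12$rows), info$c12$map_s)
  } else list()

  d1 <- if (nchi >= 1L) seq(0, 360 - chi_step, by = chi_step) else 0
  d2s <- if (nchi == 2L) seq(0, 360 - chi_step, by = chi_step) else 0
  n1 <- length(d1); n2 <- length(d2s)
  lam2 <- lambdas^2
  nl <- length(lambdas)

  centers <- bin_centers(backbone_step)
  nb <- length(centers)
  ov_grid <- if (do_ov) matrix(0, nb, nb) else NULL
  lj_grids <- if (do_lj) replicate(nl, matrix(0, nb, nb), simplify = FALSE)
              else NULL

  st <- structure
  tchi <- lapply(chis, function(ch) structure$torsions[[ch]]$atoms)

  for (ip in seq_len(nb)) {
    st <- set_torsion(st, "phi", centers[ip])
    for (is in seq_len(nb)) {
      st <- set_torsion(st, "psi", centers[is])
      X <- st$xyz

      if (nchi >= 1L) {
        p1 <- X[tchi[[1L]][2L], ]
        k1 <- vunit(X[tchi[[1L]][3L], ] - X[tchi[[1L]][2L], ])
      }
      if (nchi == 2L) {
        p2 <- X[tchi[[2L]][2L], ]
        k2 <- vunit(X[tchi[[2L]][3L], ] - X[tchi[[2L]][2L], ])
      }

      ov_mean <- 0
      e1v <- rep(0, n1); e2v <- rep(0, n2)
      e12 <- matrix(0, n1, n2); e_fix <- 0
      # min over backbone--side-chain pairs of d^2/R_s^2, per configuration
      mr_fix <- Inf; mr1 <- rep(Inf, n1); mr2 <- rep(Inf, n2)
      mr12 <- matrix(Inf, n1, n2)

      cf <- info$fix
      if (length(cf$rows)) {
        dd <- rowSums((X[cf$i, , drop = FALSE] - X[cf$j, , drop = FALSE])^2)
        if (do_ov) ov_mean <- ov_mean + sum(dd < rs2[cf$rows])
        if (do_lj) {
          e_fix <- sum(lj_energy_d2(dd, eps[cf$rows], rmin[cf$rows]))
          bb <- bbsc[cf$rows]
          if (any(bb)) mr_fix <- min(dd[bb] / rs2[cf$rows][bb])
        }
      }

      single <- function(ci, p, k, deltas) {
        P <- rotate_positions_multi(X, ci$umov, p, k, deltas)
        d2m <- matrix(0, length(ci$rows), length(deltas))
        for (d in 1:3) {
          d2m <- d2m + (P[ci$map_m, d, , drop = FALSE][, 1L, ] -
                          X[ci$stat, d])^2
        }
        d2m
      }
      for (which_c in c("c1", "c2")) {
        ci <- info[[which_c]]
        if (!length(ci$rows)) next
        if (which_c == "c1" && nchi >= 1L) {
          d2m <- single(ci, p1, k1, d1)
        } else if (which_c == "c2" && nchi == 2L) {
          d2m <- single(ci, p2, k2, d2s)
        } else next
        if (do_ov) {
          ov_mean <- ov_mean + sum(d2m < rs2[ci$rows]) / ncol(d2m)
        }
        if (do_lj) {
          ecol <- colSums(lj_energy_d2(d2m, eps[ci$rows], rmin[ci$rows]))
          bb <- bbsc[ci$rows]
          mcol <- if (any(bb)) {
            suppressWarnings(apply(d2m[bb, , drop = FALSE] /
                                     rs2[ci$rows][bb], 2L, min))
          } else rep(Inf, ncol(d2m))
          if (which_c == "c1") { e1v <- e1v + ecol; mr1 <- pmin(mr1, mcol) }
          else { e2v <- e2v + ecol; mr2 <- pmin(mr2, mcol) }
        }
      }

      ci <- info$c12
      if (length(ci$rows) && nchi == 2L) {
        S1 <- rotate_positions_multi(X, ci$ustat, p1, k1, -d1)
        P2 <- rotate_positions_multi(X, ci$umov, p2, k2, d2s)
        A2 <- apply(S1^2, c(1L, 3L), sum)   # |ustat| x n1
        B2flat <- apply(P2^2, c(1L, 3L), sum)  # |umov| x n2
        for (g in seq_along(c12_groups)) {
          rows_g <- c12_groups[[g]]
          ia <- ci$map_s[rows_g[1L]]
          sel <- ci$map_m[rows_g]
          kk <- length(sel)
          B <- matrix(aperm(P2[sel, , , drop = FALSE], c(2L, 1L, 3L)),
                      nrow = 3L)                       # 3 x (kk*n2), kk fast
          cr <- crossprod(S1[ia, , ], B)               # n1 x (kk*n2)
          b2 <- as.vector(B2flat[sel, , drop = FALSE]) # kk fast, n2 slow
          dd <- (-2 * cr + b2[col(cr)]) + A2[ia, ]
          rr <- ci$rows[rows_g]
          rs2g <- rep(rs2[rr], times = n2)
          if (do_ov) {
            ov_mean <- ov_mean +
              sum(dd < rs2g[col(dd)]) / (n1 * n2)
          }
          if (do_lj) {
            epsg <- rep(eps[rr], times = n2)
            rming <- rep(rmin[rr], times = n2)
            ev <- lj_energy_d2(dd, epsg[col(dd)], rming[col(dd)])
            dim(ev) <- c(n1, kk, n2)
            e12 <- e12 + colSums(aperm(ev, c(2L, 1L, 3L)))
            bbg <- bbsc[rr]
            if (any(bbg)) {
              rat <- dd / rs2g[col(dd)]
              dim(rat) <- c(n1, kk, n2)
              sub <- rat[, bbg, , drop = FALSE]
              mr12 <- pmin(mr12, apply(sub, c(1L, 3L), min))
            }
          }
        }
      }

      if (do_ov) ov_grid[ip, is] <- ov_mean
      if (do_lj) {
        etot <- e_fix + outer(e1v, rep(1, n2)) + outer(rep(1, n1), e2v) + e12
        mrat <- pmin(mr12, matrix(mr1, n1, n2),
                     matrix(mr2, n1, n2, byrow = TRUE), mr_fix)
        for (q in seq_len(nl)) {
          adm <- mrat > lam2[q]
          lj_grids[[q]][ip, is] <-
            if (any(adm)) mean(etot[adm]) else penalty
        }
      }
    }
  }

  list(overlap = ov_grid, lj = lj_grids, lambdas = lambdas,
       n1 = n1, n2 = n2)
}
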