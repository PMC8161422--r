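# Independent oracles and small fixture builders used across the suite.

# Exact semi-grand partition sum over all 2^n protonation states of a set
# of beads fixed in space. Chemical weight of a deprotonated site is
# 10^(pH - pKa0); electrostatics are unscreened-or-screened Coulomb
# (Lennard-Jones is state-independent and cancels). Deliberately written
# against the formulas, not against the package's sampler.
enumeration_oracle <- function(xyz, acid, pKa0, pH, lB, debye = Inf) {
  n <- nrow(xyz)
  states <- as.matrix(expand.grid(rep(list(c(1, 0)), n)))  # 1 = protonated
  d <- as.matrix(dist(xyz))
  wts <- numeric(nrow(states))
  for (k in seq_len(nrow(states))) {
    prot <- states[k, ]
    q <- ifelse(acid, ifelse(prot == 1, 0, -1), ifelse(prot == 1, 1, 0))
    U <- 0
    if (n > 1 && lB > 0) {
      for (i in 1:(n - 1)) for (j in (i + 1):n) {
        scr <- if (is.finite(debye)) exp(-d[i, j] / debye) else 1
        U <- U + lB * q[i] * q[j] * scr / d[i, j]
      }
    }
    chem <- prod(10^((pH - pKa0)[prot == 0]))
    wts[k] <- chem * exp(-U)
  }
  colSums(states * wts) / sum(wts)
}

# Topology of beads fixed in space (no conformational moves), each a
# titratable site; used to compare the sampler against the oracle.
fixed_bead_topology <- function(xyz, kinds, acid, pKa0) {
  n <- nrow(xyz)
  structure(list(
    beads = data.frame(chain = 1L, position = seq_len(n), kind = kinds,
                       x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                       flexible = FALSE, stringsAsFactors = FALSE),
    bonds = matrix(integer(0), ncol = 2),
    segments = matrix(integer(0), ncol = 3),
    sites = data.frame(bead = seq_len(n), chain = 1L,
                       position = seq_len(n), kind = kinds, acid = acid,
                       pKa0 = pKa0, stringsAsFactors = FALSE),
    mode = "monomer", n_chains = 1L), class = "mc_topology")
}

# Small PDB text fixture: one residue per row of `atoms`, which is a
# data.frame with columns resno, resid, elety, elesy, x, y, z (one or more
# atoms per residue).
write_pdb_fixture <- function(atoms, path, chain = "A") {
  lines <- character(nrow(atoms))
  for (i in seq_len(nrow(atoms))) {
    lines[i] <- sprintf(
      "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      i, atoms$elety[i], atoms$resid[i], chain, atoms$resno[i],
      atoms$x[i], atoms$y[i], atoms$z[i], atoms$elesy[i])
  }
  writeLines(c(lines, "END"), path)
  path
}

wt_spec <- function() protein_spec("wt")
q5_spec <- function() protein_spec("5Q", variant = "5Q")
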