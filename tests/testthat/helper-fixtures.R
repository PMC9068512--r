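# Shared fixture builders.  Everything is generated in code; no data
# files ship with the tests.

# The four planted gate states used across clustering tests: distinct
# chi1 rotamer patterns (one state centred at 180 degrees to exercise
# wraparound) and increasing cross-pore distances.
four_state_centroids <- function() {
  rbind(
    c(chi1_A = -60, chi1_B = -60, chi1_C = -60, chi1_D = -60,
      d625_AC = 10, d625_BD = 10, d617_AC = 8),
    c(chi1_A =  60, chi1_B =  60, chi1_C = -60, chi1_D = -60,
      d625_AC = 12, d625_BD = 12, d617_AC = 9),
    c(chi1_A = 180, chi1_B = 180, chi1_C = 180, chi1_D = 180,
      d625_AC = 14, d625_BD = 14, d617_AC = 10),
    c(chi1_A =  60, chi1_B = 180, chi1_C =  60, chi1_D = 180,
      d625_AC = 16, d625_BD = 16, d617_AC = 11))
}

sticky_transition <- function(k, stay = 0.94) {
  P <- matrix((1 - stay) / (k - 1), k, k)
  diag(P) <- stay
  P
}

# Ring of carbon-like atoms in one z-plane.
ring_model <- function(r, z, n = 8, resno = 1, chain = "A") {
  th <- 2 * pi * seq_len(n) / n
  structure_model(data.frame(
    chain = chain, resno = resno, resid = "RNG", elety = "CB",
    elesy = "C", x = r * cos(th), y = r * sin(th), z = z,
    stringsAsFactors = FALSE))
}

stack_models <- function(...) {
  structure_model(do.call(rbind, lapply(list(...), as.data.frame)))
}

# Label purity of recovered clusters against planted labels.
label_purity <- function(recovered, truth) {
  tab <- table(recovered, truth)
  sum(apply(tab, 1, max)) / length(truth)
}

# Independent dihedral oracle: atan2 of cross products, built from
# scratch (not via dihedral_angle internals).
dihedral_oracle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  x <- sum(n1 * n2)
  y <- sum(cr(n1, n2) * b2) / sqrt(sum(b2^2))
  atan2(y, x) * 180 / pi
}

# Write a minimal PDB file from coordinate rows; returns the path.
write_mini_pdb <- function(df, path = tempfile(fileext = ".pdb")) {
  lines <- vapply(seq_len(nrow(df)), function(i) {
    sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, df$elety[i], ifelse(is.null(df$alt), " ", df$alt[i]),
            df$resid[i], df$chain[i], df$resno[i],
            df$x[i], df$y[i], df$z[i],
            if (is.null(df$o)) 1 else df$o[i], 0, df$elesy[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}
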