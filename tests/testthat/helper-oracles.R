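# Independent oracles and in-code fixtures shared across the suite.

# Write raw PDB ATOM/HETATM lines without going through the package's writer,
# so read tests exercise real fixed-column input.
write_raw_pdb <- function(df, path) {
  name_field <- ifelse(nchar(df$elety) < 4, paste0(" ", df$elety), df$elety)
  lines <- sprintf(
    "%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    df$type, seq_len(nrow(df)), name_field,
    ifelse(is.null(df$alt), "", df$alt), df$resid, df$chain, df$resno,
    ifelse(is.null(df$insert), "", df$insert),
    df$x, df$y, df$z, df$o, df$b, df$elesy)
  writeLines(c(lines, "END"), path)
  path
}

# three-residue minimal protein fixture (N, CA, C per residue)
minimal_pdb <- function(path = tempfile(fileext = ".pdb")) {
  res <- data.frame(
    type = "ATOM", alt = "",
    elety = rep(c("N", "CA", "C"), 3),
    resid = rep(c("ALA", "GLY", "SER"), each = 3),
    chain = "A", resno = rep(1:3, each = 3), insert = "",
    x = rep(c(0, 1.46, 2.4), 3) + rep((0:2) * 3.8, each = 3),
    y = 0, z = 0, o = 1, b = 10,
    elesy = rep(c("N", "C", "C"), 3),
    stringsAsFactors = FALSE)
  write_raw_pdb(res, path)
}

# brute-force rigid superposition: coarse rotation grid over Euler angles,
# refined with Nelder-Mead; independent of the SVD route
grid_rmsd_oracle <- function(X, Y) {
  rotmat <- function(ang) {
    ca <- cos(ang); sa <- sin(ang)
    rz1 <- matrix(c(ca[1], -sa[1], 0, sa[1], ca[1], 0, 0, 0, 1), 3, byrow = TRUE)
    ry <- matrix(c(ca[2], 0, sa[2], 0, 1, 0, -sa[2], 0, ca[2]), 3, byrow = TRUE)
    rz2 <- matrix(c(ca[3], -sa[3], 0, sa[3], ca[3], 0, 0, 0, 1), 3, byrow = TRUE)
    rz1 %*% ry %*% rz2
  }
  Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
  obj <- function(ang) sqrt(mean(rowSums((Xc %*% t(rotmat(ang)) - Yc)^2)))
  best <- Inf; best_ang <- c(0, 0, 0)
  gr <- seq(0, 2 * pi, length.out = 13)[-13]
  for (a1 in gr) for (a2 in seq(0, pi, length.out = 7)) for (a3 in gr) {
    v <- obj(c(a1, a2, a3))
    if (v < best) { best <- v; best_ang <- c(a1, a2, a3) }
  }
  opt <- stats::optim(best_ang, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}

# analytic accessible area of two equal spheres of extended radius R at
# center distance d < 2R: each loses a cap of area 2*pi*R*h, h = R - d/2
two_sphere_exposed_area <- function(R, d) {
  h <- R - d / 2
  2 * (4 * pi * R^2 - 2 * pi * R * h)
}

random_rotation <- function(seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
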