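# Independent oracles used across the suite.

# Horn's quaternion method for optimal-superposition RMSD: an independent
# route (largest eigenvalue of the 4x4 quaternion matrix) to the same
# quantity superpose() computes via Kabsch/SVD.
quaternion_rmsd <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  A0 <- sweep(A, 2, colMeans(A)); B0 <- sweep(B, 2, colMeans(B))
  S <- crossprod(A0, B0)
  K <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2], S[3,1]-S[1,3], S[1,2]-S[2,1],
    S[2,3]-S[3,2], S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1], S[3,1]+S[1,3],
    S[3,1]-S[1,3], S[1,2]+S[2,1], -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1], S[3,1]+S[1,3], S[2,3]+S[3,2], -S[1,1]-S[2,2]+S[3,3]),
    4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(A0^2) + sum(B0^2) - 2 * lam) / nrow(A)
  sqrt(max(0, msd))
}

# analytic per-sphere exposed area for two equal spheres of expanded radius
# R at centre distance d (0 < d < 2R): exposed fraction (1 + d/(2R))/2
two_sphere_exposed_area <- function(R, d) (1 + d / (2 * R)) / 2 * 4 * pi * R^2

# random rigid transform applied to every frame of a trajectory
random_rigid <- function(seed) {
  set.seed(seed)
  th <- runif(3, 0, 2 * pi)
  Rx <- matrix(c(1,0,0, 0,cos(th[1]),-sin(th[1]), 0,sin(th[1]),cos(th[1])),3,3)
  Ry <- matrix(c(cos(th[2]),0,sin(th[2]), 0,1,0, -sin(th[2]),0,cos(th[2])),3,3)
  Rz <- matrix(c(cos(th[3]),-sin(th[3]),0, sin(th[3]),cos(th[3]),0, 0,0,1),3,3)
  list(R = Rx %*% Ry %*% Rz, t = runif(3, -20, 20))
}

transform_traj <- function(traj, rt) {
  traj$coords <- lapply(traj$coords, function(m)
    sweep(m %*% t(rt$R), 2, rt$t, "+"))
  traj
}

mols_from_smiles <- function(smis) {
  sdf <- ChemmineR::smiles2sdf(stats::setNames(smis, smis))
  lapply(seq_along(smis), function(i) mol_from_sdf(sdf[[i]], smis[i]))
}
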