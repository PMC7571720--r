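# Independent oracles used across tests.

# closed-form occupancy of a single regulatory unit: 4-state linear balance
# over (UN, BN, UP, BP) with both neighbours fixed at n permissive states;
# returns the permissive probability.  Built directly from the named
# constants, independent of the package's rhs code paths.
single_ru_P <- function(ru, Ca, n = 0) {
  kd <- ru$kd_bar
  kUB <- (ru$koff / kd) * Ca
  kBU_N <- ru$koff
  kBU_P <- ru$koff / ru$mu
  kNP_U <- (ru$Q / ru$mu) * ru$kbasic * ru$gamma^n
  kNP_B <- ru$Q * ru$kbasic * ru$gamma^n
  kPN <- ru$kbasic * ru$gamma^(2 - n)
  G <- matrix(0, 4, 4)
  G[1, 2] <- kUB;   G[2, 1] <- kBU_N
  G[3, 4] <- kUB;   G[4, 3] <- kBU_P
  G[1, 3] <- kNP_U; G[3, 1] <- kPN
  G[2, 4] <- kNP_B; G[4, 2] <- kPN
  diag(G) <- -rowSums(G)
  A <- t(G); A[4, ] <- 1
  p <- solve(A, c(0, 0, 0, 1))
  sum(p[3:4])
}

# a small geometry reused by chain tests
geom_n <- function(n) sarcomere_geometry(n_ru = n)

rat_mf <- function() sarcomere_preset("rat_room", "MF")
rat_se <- function() sarcomere_preset("rat_room", "SE")
human_mf <- function() sarcomere_preset("human_body", "MF")
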