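#' Mass-action time derivative of an Hfq network
#'
#' Evaluates the exact mass-action right-hand side of the ODE system for a
#' network state.  Free Hfq is produced at `alpha_H`, regained when an RNA
#' dissociates from a singly-bound complex and when a ternary complex
#' anneals and releases its duplex (Hfq recycling), and consumed by RNA
#' binding.  Ternary complexes form through the two branches (mRNA joining
#' `HS_i`, or sRNA joining `HT_j`) and are drained by dissociation of either
#' RNA, by annealing (`k5`), and by degradation.  Duplexes are produced only
#' by annealing and removed only by degradation: they never rebind Hfq.
#' Every species additionally decays at `beta` (or its override).
#'
#' @param net An [hfq_network()].
#' @param state Numeric state vector (see [pack_state()]) or the list form
#'   returned by [unpack_state()].
#' @return A named numeric vector of derivatives, in the state layout.
#' @examples
#' net <- hfq_network(1, 1, k1 = 1, k2 = 1, k3 = 1, k4 = 1, k5 = 10)
#' derivatives(net, pack_state(net)) # pure production at the origin
#' @export
derivatives <- function(net, state) {
  if (is.list(state)) state <- do.call(pack_state, c(list(net), state))
  n <- net$n_srna; m <- net$m_mrna
  if (length(state) != state_dimension(net))
    stop(sprintf("state has length %d, expected %d",
                 length(state), state_dimension(net)), call. = FALSE)
  s <- unpack_state(net, state)
  H <- s$H; S <- s$S; T <- s$T; HS <- s$HS; HT <- s$HT
  HST <- s$HST; D <- s$D

  # bimolecular fluxes
  bind1 <- net$k1 * S * H                  # S_i + H -> HS_i
  bind2 <- net$k2 * T * H                  # T_j + H -> HT_j
  bind3 <- net$k3 * outer(HS, T)           # T_j + HS_i -> HST_ij
  bind4 <- net$k4 * outer(S, HT)           # S_i + HT_j -> HST_ij
  dis3 <- net$kneg3 * HST                  # HST_ij -> HS_i + T_j
  dis4 <- net$kneg4 * HST                  # HST_ij -> HT_j + S_i
  anneal <- net$k5 * HST                   # HST_ij -> D_ij + H

  dH <- net$alpha_H + sum(net$kneg1 * HS) + sum(net$kneg2 * HT) +
    sum(anneal) - sum(bind1) - sum(bind2)
  dS <- net$alpha_S + net$kneg1 * HS + rowSums(dis4) - bind1 - rowSums(bind4)
  dT <- net$alpha_T + net$kneg2 * HT + colSums(dis3) - bind2 - colSums(bind3)
  dHS <- bind1 + rowSums(dis3) - net$kneg1 * HS - rowSums(bind3)
  dHT <- bind2 + colSums(dis4) - net$kneg2 * HT - colSums(bind4)
  dHST <- bind3 + bind4 - dis3 - dis4 - anneal
  dD <- anneal

  out <- c(dH, dS, dT, dHS, dHT, as.numeric(t(dHST)), as.numeric(t(dD))) -
    beta_vector(net) * state
  names(out) <- state_names(net)
  out
}

#' Jacobian of the mass-action derivative
#'
#' Dense analytic Jacobian of [derivatives()] with respect to the state,
#' used both by the stiff integrator and by the Newton steady-state solvers.
#'
#' @inheritParams derivatives
#' @return A square matrix of dimension [state_dimension()].
#' @export
jacobian <- function(net, state) {
  if (is.list(state)) state <- do.call(pack_state, c(list(net), state))
  n <- net$n_srna; m <- net$m_mrna
  s <- unpack_state(net, state)
  H <- s$H; S <- s$S; T <- s$T; HS <- s$HS; HT <- s$HT
  idx <- state_index(n, m)
  N <- state_dimension(net)
  J <- matrix(0, N, N)

  # row-major (i, j) -> flat offset within an n*m block
  pos <- function(i, j) (i - 1L) * m + j

  # H row
  J[idx$H, idx$H] <- -(sum(net$k1 * S) + sum(net$k2 * T))
  J[idx$H, idx$S] <- -net$k1 * H
  J[idx$H, idx$T] <- -net$k2 * H
  J[idx$H, idx$HS] <- net$kneg1
  J[idx$H, idx$HT] <- net$kneg2
  J[idx$H, idx$HST] <- as.numeric(t(net$k5))

  # S rows
  for (i in seq_len(n)) {
    r <- idx$S[i]
    J[r, idx$H] <- -net$k1[i] * S[i]
    J[r, idx$S[i]] <- -net$k1[i] * H - sum(net$k4[i, ] * HT)
    J[r, idx$HS[i]] <- net$kneg1[i]
    J[r, idx$HT] <- -net$k4[i, ] * S[i]
    J[r, idx$HST[pos(i, seq_len(m))]] <- net$kneg4[i, ]
  }

  # T rows
  for (j in seq_len(m)) {
    r <- idx$T[j]
    J[r, idx$H] <- -net$k2[j] * T[j]
    J[r, idx$T[j]] <- -net$k2[j] * H - sum(net$k3[, j] * HS)
    J[r, idx$HT[j]] <- net$kneg2[j]
    J[r, idx$HS] <- -net$k3[, j] * T[j]
    J[r, idx$HST[pos(seq_len(n), j)]] <- net$kneg3[, j]
  }

  # HS rows
  for (i in seq_len(n)) {
    r <- idx$HS[i]
    J[r, idx$H] <- net$k1[i] * S[i]
    J[r, idx$S[i]] <- net$k1[i] * H
    J[r, idx$T] <- -net$k3[i, ] * HS[i]
    J[r, idx$HS[i]] <- -net$kneg1[i] - sum(net$k3[i, ] * T)
    J[r, idx$HST[pos(i, seq_len(m))]] <- net$kneg3[i, ]
  }

  # HT rows
  for (j in seq_len(m)) {
    r <- idx$HT[j]
    J[r, idx$H] <- net$k2[j] * T[j]
    J[r, idx$T[j]] <- net$k2[j] * H
    J[r, idx$S] <- -net$k4[, j] * HT[j]
    J[r, idx$HT[j]] <- -net$kneg2[j] - sum(net$k4[, j] * S)
    J[r, idx$HST[pos(seq_len(n), j)]] <- net$kneg4[, j]
  }

  # HST and D rows
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      r <- idx$HST[pos(i, j)]
      J[r, idx$S[i]] <- net$k4[i, j] * HT[j]
      J[r, idx$T[j]] <- net$k3[i, j] * HS[i]
      J[r, idx$HS[i]] <- net$k3[i, j] * T[j]
      J[r, idx$HT[j]] <- net$k4[i, j] * S[i]
      J[r, r] <- -(net$kneg3[i, j] + net$kneg4[i, j] + net$k5[i, j])
      J[idx$D[pos(i, j)], r] <- net$k5[i, j]
    }
  }

  diag(J) <- diag(J) - beta_vector(net)
  J
}
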