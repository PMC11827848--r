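#' Pair residues of two chains across insertions and deletions
#'
#' Matches the residues of two chains one-to-one by global alignment of their
#' one-letter sequences (Needleman-Wunsch; match +1, mismatch -1, gap -2;
#' ties broken preferring diagonal, then the gap consuming chain A).
#' Identical sequences pair positionally; a single-residue deletion in chain
#' B leaves exactly the deleted residue of chain A unpaired -- the situation
#' created by the K210 deletion in TnnT.
#'
#' @param res_a,res_b residue tables as returned by [chain_residues()], or
#'   models paired with `chain_a`/`chain_b`.
#' @param chain_a,chain_b chain ids, required when models are supplied.
#' @return object of class `residue_pairing`: data.frame with columns
#'   `chain_a`, `resseq_a`, `icode_a`, `aa_a`, `chain_b`, `resseq_b`,
#'   `icode_b`, `aa_b`; attributes `unpaired_a` and `unpaired_b` hold the
#'   residues without a partner.
#' @export
pair_residues <- function(res_a, res_b, chain_a = NULL, chain_b = NULL) {
  if (inherits(res_a, "structure_model")) {
    stopifnot(!is.null(chain_a))
    res_a <- chain_residues(res_a, chain_a)
  }
  if (inherits(res_b, "structure_model")) {
    stopifnot(!is.null(chain_b))
    res_b <- chain_residues(res_b, chain_b)
  }
  if (nrow(res_a) == 0 || nrow(res_b) == 0) stop("empty chain in pairing")
  aln <- needleman_wunsch(res_a$aa, res_b$aa)
  ia <- aln$i_a
  ib <- aln$i_b
  paired <- !is.na(ia) & !is.na(ib)
  pairs <- data.frame(
    chain_a = res_a$chain[ia[paired]], resseq_a = res_a$resseq[ia[paired]],
    icode_a = res_a$icode[ia[paired]], aa_a = res_a$aa[ia[paired]],
    chain_b = res_b$chain[ib[paired]], resseq_b = res_b$resseq[ib[paired]],
    icode_b = res_b$icode[ib[paired]], aa_b = res_b$aa[ib[paired]],
    stringsAsFactors = FALSE)
  ua <- res_a[setdiff(seq_len(nrow(res_a)), ia[paired]), , drop = FALSE]
  ub <- res_b[setdiff(seq_len(nrow(res_b)), ib[paired]), , drop = FALSE]
  rownames(pairs) <- rownames(ua) <- rownames(ub) <- NULL
  structure(pairs, unpaired_a = ua, unpaired_b = ub,
            score = aln$score, class = c("residue_pairing", "data.frame"))
}

#' @export
print.residue_pairing <- function(x, ...) {
  ua <- attr(x, "unpaired_a")
  ub <- attr(x, "unpaired_b")
  if (is.null(ua)) ua <- data.frame()
  if (is.null(ub)) ub <- data.frame()
  cat("residue_pairing: ", nrow(x), " pairs, ",
      nrow(ua), " unpaired in A, ",
      nrow(ub), " unpaired in B\n", sep = "")
  if (nrow(ua))
    cat("  unpaired A:", paste0(ua$chain, ":", ua$resname, ua$resseq,
                                collapse = " "), "\n")
  if (nrow(ub))
    cat("  unpaired B:", paste0(ub$chain, ":", ub$resname, ub$resseq,
                                collapse = " "), "\n")
  invisible(x)
}

#' Global sequence alignment (Needleman-Wunsch)
#'
#' Linear gap penalty; deterministic traceback (on ties: diagonal first, then
#' up = gap in B, then left = gap in A).
#'
#' @param a,b character vectors of one-letter residue codes.
#' @param match,mismatch,gap scoring parameters.
#' @return list with `i_a`, `i_b` (aligned index vectors, NA at gaps) and
#'   `score`.
#' @export
needleman_wunsch <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  n <- length(a)
  m <- length(b)
  stopifnot(n > 0, m > 0)
  F <- matrix(0, n + 1, m + 1)
  P <- matrix(0L, n + 1, m + 1)  # 1 diag, 2 up, 3 left
  F[, 1] <- gap * (0:n)
  F[1, ] <- gap * (0:m)
  P[, 1] <- 2L
  P[1, ] <- 3L
  P[1, 1] <- 0L
  for (i in seq_len(n)) {
    si <- ifelse(b == a[i], match, mismatch)
    for (j in seq_len(m)) {
      d <- F[i, j] + si[j]
      u <- F[i, j + 1] + gap
      l <- F[i + 1, j] + gap
      best <- max(d, u, l)
      F[i + 1, j + 1] <- best
      P[i + 1, j + 1] <- if (d == best) 1L else if (u == best) 2L else 3L
    }
  }
  i <- n + 1
  j <- m + 1
  ia <- integer(0)
  ib <- integer(0)
  while (i > 1 || j > 1) {
    p <- P[i, j]
    if (p == 1L) {
      ia <- c(i - 1L, ia); ib <- c(j - 1L, ib); i <- i - 1L; j <- j - 1L
    } else if (p == 2L) {
      ia <- c(i - 1L, ia); ib <- c(NA, ib); i <- i - 1L
    } else {
      ia <- c(NA, ia); ib <- c(j - 1L, ib); j <- j - 1L
    }
  }
  list(i_a = ia, i_b = ib, score = F[n + 1, m + 1])
}

#' Pair all chains of two protomers role by role
#'
#' Convenience wrapper: pairs the TnnC, TnnT and TnnI chains of a protomer in
#' each model and concatenates the pairings.
#'
#' @param model_a,model_b [structure_model]s.
#' @param roles_a,roles_b their [assign_roles()] maps.
#' @param protomer_a,protomer_b protomer labels (default `"A"`).
#' @param roles roles to pair (default the three troponin chains present in
#'   both maps).
#' @return `residue_pairing` with an extra `role` column.
#' @export
pair_protomers <- function(model_a, model_b, roles_a, roles_b,
                           protomer_a = "A", protomer_b = "A",
                           roles = NULL) {
  if (is.null(roles))
    roles <- intersect(intersect(roles_a$role, roles_b$role),
                       c("TnnC", "TnnT", "TnnI"))
  if (length(roles) == 0)
    stop("no common troponin roles between the two models")
  per_role <- lapply(roles, function(r) {
    ch_a <- role_chain(roles_a, r, protomer_a)
    ch_b <- role_chain(roles_b, r, protomer_b)
    pair_residues(model_a, model_b, chain_a = ch_a, chain_b = ch_b)
  })
  parts <- Map(function(r, p) cbind(role = r, as.data.frame(p),
                                    stringsAsFactors = FALSE),
               roles, per_role)
  ua <- do.call(rbind, lapply(per_role, attr, "unpaired_a"))
  ub <- do.call(rbind, lapply(per_role, attr, "unpaired_b"))
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  structure(out, unpaired_a = ua, unpaired_b = ub,
            class = c("residue_pairing", "data.frame"))
}
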