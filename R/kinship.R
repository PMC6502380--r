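#' Additive relationship (numerator) matrix from a pedigree
#'
#' Recursive tabular method over the topologically sorted pedigree:
#' `A[i,i] = 1 + A[sire,dam]/2`, `A[i,j] = (A[j,sire] + A[j,dam])/2`.
#' Unrelated founders get 0 off-diagonal and 1 on the diagonal; full sibs of
#' unrelated parents 0.5, half sibs 0.25.
#'
#' @param pedigree validated pedigree data.frame
#' @param ids individuals to return (subset of the pedigree); default all
#' @return symmetric matrix with dimnames `ids`
#' @export
pedigree_kinship <- function(pedigree, ids = NULL) {
  ped <- validate_pedigree(as.data.frame(pedigree))
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$individual_id)
  if (is.null(ids)) ids <- ped$individual_id
  if (!all(ids %in% ped$individual_id))
    stop_ctx("pedigree_kinship: id '%s' not in pedigree",
             setdiff(ids, ped$individual_id)[1])
  s <- idx[ped$sire_id]
  d <- idx[ped$dam_id]
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    if (is.na(si) && is.na(di)) {
      A[i, i] <- 1
    } else {
      prev <- seq_len(i - 1L)
      rs <- if (is.na(si)) rep(0, i - 1L) else A[si, prev]
      rd <- if (is.na(di)) rep(0, i - 1L) else A[di, prev]
      if (i > 1L) {
        A[i, prev] <- (rs + rd) / 2
        A[prev, i] <- A[i, prev]
      }
      A[i, i] <- 1 + (if (is.na(si) || is.na(di)) 0 else A[si, di] / 2)
    }
  }
  dimnames(A) <- list(ped$individual_id, ped$individual_id)
  A[ids, ids, drop = FALSE]
}
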