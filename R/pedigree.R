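#' Validate a pedigree table
#'
#' Checks id uniqueness, that every named parent exists as an individual,
#' acyclicity (via topological sort), and — when a `cohort` column is
#' present — that parents are born strictly before their offspring.
#'
#' @param pedigree data.frame with columns `id`, `dam`, `sire` (NA for
#'   unknown parents) and optionally `cohort`.
#' @return the pedigree, invisibly, with a `topo_order` attribute (row order
#'   in which every parent precedes its offspring).
#' @export
validate_pedigree <- function(pedigree) {
  stopifnot(all(c("id", "dam", "sire") %in% names(pedigree)))
  id <- as.character(pedigree$id)
  if (anyDuplicated(id))
    stop("duplicate individual id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  parents <- c(pedigree$dam, pedigree$sire)
  missing <- setdiff(stats::na.omit(as.character(parents)), id)
  if (length(missing))
    stop("parent id(s) not present as individuals: ",
         paste(utils::head(missing, 5), collapse = ", "))

  n <- length(id)
  idx <- stats::setNames(seq_len(n), id)
  dam <- ifelse(is.na(pedigree$dam), 0L, idx[as.character(pedigree$dam)])
  sire <- ifelse(is.na(pedigree$sire), 0L, idx[as.character(pedigree$sire)])

  # Kahn's algorithm: parents before offspring
  indeg <- (dam > 0L) + (sire > 0L)
  children <- split(rep(seq_len(n), 2), c(dam, sire))
  children[["0"]] <- NULL
  queue <- which(indeg == 0L)
  topo <- integer(n)
  k <- 0L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    k <- k + 1L
    topo[k] <- v
    for (ch in children[[as.character(v)]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (k < n)
    stop("pedigree contains a cycle involving: ",
         paste(utils::head(id[indeg > 0L], 5), collapse = ", "))

  if ("cohort" %in% names(pedigree)) {
    co <- pedigree$cohort
    bad <- (dam > 0L & co[pmax(dam, 1L)] >= co) |
      (sire > 0L & co[pmax(sire, 1L)] >= co)
    if (any(bad))
      stop("parent cohort not earlier than offspring cohort for: ",
           paste(utils::head(id[bad], 5), collapse = ", "))
  }
  attr(pedigree, "topo_order") <- topo
  invisible(pedigree)
}

ped_indices <- function(pedigree) {
  id <- as.character(pedigree$id)
  idx <- stats::setNames(seq_along(id), id)
  list(id = id,
       dam = unname(ifelse(is.na(pedigree$dam), 0L,
                           idx[as.character(pedigree$dam)])),
       sire = unname(ifelse(is.na(pedigree$sire), 0L,
                            idx[as.character(pedigree$sire)])))
}

#' Dense additive (numerator) relationship matrix
#'
#' Tabular method: A(i,i) = 1 + F_i with F_i half the relationship of the
#' parents, and A(i,j) the mean of j's relationships to i's parents.
#' Intended for small pedigrees and as the independent oracle for the
#' sparse inverse.
#'
#' @inheritParams validate_pedigree
#' @return dense matrix with dimnames = ids.
#' @export
amatrix <- function(pedigree) {
  pedigree <- validate_pedigree(pedigree)
  topo <- attr(pedigree, "topo_order")
  p <- ped_indices(pedigree)
  n <- length(p$id)
  A <- matrix(0, n, n, dimnames = list(p$id, p$id))
  done <- integer(0)
  for (i in topo) {
    d <- p$dam[i]; s <- p$sire[i]
    A[i, i] <- 1 + if (d > 0L && s > 0L) 0.5 * A[d, s] else 0
    if (length(done)) {
      aj <- 0.5 * ((if (d > 0L) A[d, done] else 0) +
                     (if (s > 0L) A[s, done] else 0))
      A[i, done] <- aj
      A[done, i] <- aj
    }
    done <- c(done, i)
  }
  A
}

#' Sparse inverse of the additive relationship matrix
#'
#' Henderson's rules with inbreeding: for individual `i` with parents `d`
#' and `s`, the Mendelian-sampling variance is
#' `m_i = 0.5 - 0.25 (F_d + F_s)` when both parents are known,
#' `0.75 - 0.25 F_p` with one known parent, and `1` with none; with
#' `alpha_i = 1/m_i`, individual `i` contributes `alpha` to cell (i,i),
#' `-alpha/2` to each (i, parent) pair and `alpha/4` to each parent-parent
#' cell. Inbreeding coefficients come from the Meuwissen-Luo traversal of
#' the tabular relationship matrix restricted to ancestors, so founders are
#' mutually unrelated and non-inbred by construction.
#'
#' @inheritParams validate_pedigree
#' @param inbreeding compute inbreeding coefficients (default) or assume a
#'   non-inbred pedigree.
#' @return list of class `rn_relmat`: `Ainv` (sparse `dgCMatrix`, dimnames =
#'   ids), `F` (named inbreeding coefficients), `ids`.
#' @examples
#' ped <- data.frame(id = c("d", "s", "o"), dam = c(NA, NA, "d"),
#'                   sire = c(NA, NA, "s"))
#' build_relationship_inverse(ped)$Ainv
#' @export
build_relationship_inverse <- function(pedigree, inbreeding = TRUE) {
  pedigree <- validate_pedigree(pedigree)
  topo <- attr(pedigree, "topo_order")
  p <- ped_indices(pedigree)
  n <- length(p$id)
  F <- if (inbreeding) {
    meuwissen_luo_F(p$dam, p$sire, topo)
  } else numeric(n)

  Fd <- ifelse(p$dam > 0L, F[pmax(p$dam, 1L)], NA_real_)
  Fs <- ifelse(p$sire > 0L, F[pmax(p$sire, 1L)], NA_real_)
  nk <- (p$dam > 0L) + (p$sire > 0L)
  m <- ifelse(nk == 2L, 0.5 - 0.25 * (Fd + Fs),
              ifelse(nk == 1L, 0.75 - 0.25 * pmax(Fd, Fs, na.rm = TRUE), 1))
  a <- 1 / m

  i <- seq_len(n)
  hd <- p$dam > 0L; hs <- p$sire > 0L; hb <- hd & hs
  ii <- c(i, i[hd], p$dam[hd], p$dam[hd], i[hs], p$sire[hs], p$sire[hs],
          p$dam[hb], p$sire[hb])
  jj <- c(i, p$dam[hd], i[hd], p$dam[hd], p$sire[hs], i[hs], p$sire[hs],
          p$sire[hb], p$dam[hb])
  xx <- c(a, -a[hd] / 2, -a[hd] / 2, a[hd] / 4, -a[hs] / 2, -a[hs] / 2,
          a[hs] / 4, a[hb] / 4, a[hb] / 4)
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(p$id, p$id))
  structure(list(Ainv = Ainv, F = stats::setNames(F, p$id), ids = p$id),
            class = "rn_relmat")
}

# Meuwissen & Luo (1992): F_i = A(i,i) - 1 accumulated over ancestor paths.
# Thin wrapper over the compiled traversal.
meuwissen_luo_F <- function(dam, sire, topo) {
  as.numeric(ml_inbreeding(as.integer(dam), as.integer(sire),
                           as.integer(topo)))
}

#' Permute pedigree links (negative control)
#'
#' Randomly reassigns each non-founder's parents to a parent pair drawn from
#' the pedigree's existing pairs of an earlier cohort, destroying the true
#' relatedness structure while preserving its shape. Used to show that
#' additive-genetic variance estimates collapse when the pedigree carries no
#' information.
#'
#' @inheritParams validate_pedigree
#' @return a pedigree data.frame of the same shape.
#' @export
permute_pedigree <- function(pedigree) {
  pedigree <- validate_pedigree(pedigree)
  ped <- as.data.frame(pedigree)
  nonf <- which(!is.na(ped$dam) | !is.na(ped$sire))
  if (!length(nonf)) return(ped)
  pairs <- unique(data.frame(dam = ped$dam[nonf], sire = ped$sire[nonf],
                             stringsAsFactors = FALSE))
  if ("cohort" %in% names(ped)) {
    co <- stats::setNames(ped$cohort, as.character(ped$id))
    pair_max <- pmax(co[as.character(pairs$dam)], co[as.character(pairs$sire)])
    for (i in nonf) {
      ok <- which(pair_max < ped$cohort[i])
      if (length(ok)) {
        k <- ok[sample.int(length(ok), 1)]
        ped$dam[i] <- pairs$dam[k]; ped$sire[i] <- pairs$sire[k]
      }
    }
  } else {
    k <- sample.int(nrow(pairs), length(nonf), replace = TRUE)
    ped$dam[nonf] <- pairs$dam[k]; ped$sire[nonf] <- pairs$sire[k]
  }
  validate_pedigree(ped)
  ped
}
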