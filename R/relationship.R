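#' Additive relationship matrix from a pedigree
#'
#' Recursive tabular method: founders are taken as unrelated and
#' non-inbred; each individual's relationships are the average of its
#' parents' rows and its diagonal is \eqn{1 + F} with inbreeding
#' \eqn{F = a_{sd}/2}. Individuals are topologically sorted internally, so
#' any input order is accepted.
#'
#' @param pedigree data.frame with columns id, sire, dam (character; NA or
#'   "" for unknown parents).
#' @return Dense symmetric matrix with ids as dimnames.
#' @examples
#' ped <- data.frame(id = c("f1", "f2", "kid"),
#'                   sire = c(NA, NA, "f1"), dam = c(NA, NA, "f2"))
#' buildA(ped)["f1", "kid"]  # 0.5
#' @export
buildA <- function(pedigree) {
  stopifnot(all(c("id", "sire", "dam") %in% names(pedigree)))
  id <- as.character(pedigree$id)
  if (anyDuplicated(id)) stop("duplicated ids in pedigree")
  clean <- function(x) {
    x <- as.character(x)
    x[!is.na(x) & x == ""] <- NA_character_
    x
  }
  sire <- clean(pedigree$sire)
  dam <- clean(pedigree$dam)
  bad <- setdiff(c(sire, dam), c(id, NA))
  if (length(bad))
    stop("unknown parent id(s): ", paste(utils::head(bad, 5), collapse = ", "))

  n <- length(id)
  si <- match(sire, id)
  di <- match(dam, id)
  ## topological sort; failure to make progress means a cycle
  done <- logical(n)
  ord <- integer(n)
  filled <- 0L
  parentReady <- function(p) is.na(p) | done[pmax(p, 1L)]
  while (filled < n) {
    ready <- which(!done & parentReady(si) & parentReady(di))
    if (!length(ready))
      stop("pedigree contains a cycle involving: ",
           paste(utils::head(id[!done], 10), collapse = ", "))
    ord[filled + seq_along(ready)] <- ready
    done[ready] <- TRUE
    filled <- filled + length(ready)
  }

  A <- matrix(0, n, n, dimnames = list(id, id))
  for (t in seq_len(n)) {
    i <- ord[t]
    s <- si[i]; d <- di[i]
    if (t > 1L) {
      prev <- ord[seq_len(t - 1L)]
      rs <- if (is.na(s)) 0 else A[s, prev]
      rd <- if (is.na(d)) 0 else A[d, prev]
      A[i, prev] <- A[prev, i] <- 0.5 * (rs + rd)
    }
    A[i, i] <- 1 + if (is.na(s) || is.na(d)) 0 else 0.5 * A[s, d]
  }
  A
}

#' Restrict a pedigree to some individuals and their ancestors
#'
#' @param pedigree data.frame with id, sire, dam.
#' @param keep Character ids to retain (ancestors are added automatically).
#' @return The pruned pedigree, ancestors first.
#' @export
prunePedigree <- function(pedigree, keep) {
  id <- as.character(pedigree$id)
  need <- unique(as.character(keep))
  repeat {
    rows <- match(need, id)
    parents <- stats::na.omit(unique(c(pedigree$sire[rows],
                                       pedigree$dam[rows])))
    parents <- setdiff(parents, c(need, ""))
    if (!length(parents)) break
    need <- c(need, parents)
  }
  out <- pedigree[id %in% need, , drop = FALSE]
  out[order(match(out$id, id)), , drop = FALSE]
}
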