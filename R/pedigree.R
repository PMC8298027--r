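#' Generate a two-generation full-sib pedigree
#'
#' Builds the mating design of the study population: unrelated founder pairs
#' (one sire, one dam per family) produce generation-1 full-sib families of
#' random size; generation-2 families are produced by mating generation-1
#' individuals drawn from distinct generation-1 families, each individual used
#' as a parent at most once.
#'
#' @param config a [sim_config()] object. The random seed is `config$seed`.
#' @return a `data.frame` with columns `id`, `sire`, `dam` (integer, 0 =
#'   unknown parent) and `generation` (0 = founder). Parents always precede
#'   their offspring.
#' @export
make_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nf1 <- config$families_gen1
  nf2 <- config$families_gen2
  n_founders <- 2L * nf1
  ped <- data.frame(id = seq_len(n_founders), sire = 0L, dam = 0L,
                    generation = 0L)
  next_id <- n_founders + 1L
  fam_of <- integer(0)   # gen-1 family index per gen-1 individual
  g1_ids <- integer(0)
  draw_size <- function(rng) {
    if (rng[1] == rng[2]) rng[1] else sample(seq(rng[1], rng[2]), 1L)
  }
  for (f in seq_len(nf1)) {
    sire <- 2L * f - 1L
    dam <- 2L * f
    n_off <- draw_size(config$offspring_gen1)
    ids <- seq(next_id, length.out = n_off)
    ped <- rbind(ped, data.frame(id = ids, sire = sire, dam = dam,
                                 generation = 1L))
    fam_of <- c(fam_of, rep(f, n_off))
    g1_ids <- c(g1_ids, ids)
    next_id <- next_id + n_off
  }
  if (nf2 > 0) {
    # pair gen-1 individuals from distinct families, each used at most once
    if (length(g1_ids) < 2L * nf2)
      stop("impossible mating structure: ", length(g1_ids),
           " generation-1 candidates for ", 2L * nf2, " parent slots")
    ord <- sample(seq_along(g1_ids))
    avail <- ord
    pairs <- matrix(0L, nrow = nf2, ncol = 2L)
    for (f in seq_len(nf2)) {
      i <- avail[1]
      j_pos <- which(fam_of[avail] != fam_of[i])[1]
      if (is.na(j_pos))
        stop("impossible mating structure: cannot pair parents from ",
             "distinct generation-1 families for gen-2 family ", f)
      j <- avail[j_pos]
      pairs[f, ] <- c(g1_ids[i], g1_ids[j])
      avail <- setdiff(avail, c(i, j))
    }
    for (f in seq_len(nf2)) {
      n_off <- draw_size(config$offspring_gen2)
      ids <- seq(next_id, length.out = n_off)
      ped <- rbind(ped, data.frame(id = ids, sire = pairs[f, 1],
                                   dam = pairs[f, 2], generation = 2L))
      next_id <- next_id + n_off
    }
  }
  rownames(ped) <- NULL
  ped
}

#' Write / read a pedigree as 4-column whitespace-delimited text
#'
#' Columns: id, sire, dam, generation; 0 denotes an unknown parent.
#'
#' @param ped pedigree `data.frame` as returned by [make_pedigree()].
#' @param path file path.
#' @return `read_pedigree` returns the pedigree `data.frame`;
#'   `write_pedigree` returns `path` invisibly.
#' @export
write_pedigree <- function(ped, path) {
  utils::write.table(ped[, c("id", "sire", "dam", "generation")], path,
                     row.names = FALSE, col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.table(path, header = TRUE)
  stopifnot(all(c("id", "sire", "dam", "generation") %in% names(ped)))
  ped
}

# Topological order: parents before offspring. Errors on a cycle.
pedigree_order <- function(ped) {
  ids <- ped$id
  idx <- stats::setNames(seq_along(ids), ids)
  parent_idx <- cbind(
    ifelse(ped$sire == 0, NA_integer_, idx[as.character(ped$sire)]),
    ifelse(ped$dam == 0, NA_integer_, idx[as.character(ped$dam)]))
  known <- c(ped$sire, ped$dam)
  known <- known[known != 0]
  if (!all(known %in% ids))
    stop("pedigree references unknown parent id(s): ",
         paste(utils::head(setdiff(known, ids), 5), collapse = ", "))
  placed <- logical(nrow(ped))
  ord <- integer(0)
  repeat {
    ready <- which(!placed &
                   (is.na(parent_idx[, 1]) | placed[parent_idx[, 1]]) &
                   (is.na(parent_idx[, 2]) | placed[parent_idx[, 2]]))
    if (length(ready) == 0L) break
    placed[ready] <- TRUE
    ord <- c(ord, ready)
  }
  if (length(ord) < nrow(ped))
    stop("pedigree loop detected involving id(s): ",
         paste(utils::head(ids[!placed], 5), collapse = ", "))
  ord
}

#' Pedigree numerator relationship matrix (A)
#'
#' Computes the additive numerator relationship matrix by the tabular
#' (recursive) method: `A[i,i] = 1 + 0.5 * A[sire, dam]` and
#' `A[i,j] = 0.5 * (A[j, sire] + A[j, dam])`, with unknown parents
#' contributing zero. The diagonal equals 1 + F (inbreeding coefficient).
#'
#' @param ped pedigree `data.frame` (id, sire, dam); any order, sorted
#'   internally so parents precede offspring. A pedigree loop is an error.
#' @return a [relmat] of kind `"A"` with row/column names equal to the
#'   pedigree ids.
#' @export
nrm <- function(ped) {
  ord <- pedigree_order(ped)
  ped <- ped[ord, ]
  n <- nrow(ped)
  ids <- as.character(ped$id)
  idx <- stats::setNames(seq_len(n), ids)
  s <- ifelse(ped$sire == 0, 0L, idx[as.character(ped$sire)])
  d <- ifelse(ped$dam == 0, 0L, idx[as.character(ped$dam)])
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    asd <- if (s[i] > 0 && d[i] > 0) A[s[i], d[i]] else 0
    A[i, i] <- 1 + 0.5 * asd
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row_s <- if (s[i] > 0) A[s[i], j] else 0
      row_d <- if (d[i] > 0) A[d[i], j] else 0
      aij <- 0.5 * (row_s + row_d)
      A[i, j] <- aij
      A[j, i] <- aij
    }
  }
  relmat(A, kind = "A")
}
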