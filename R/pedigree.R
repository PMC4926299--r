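#' Construct and validate a pedigree table
#'
#' A pedigree table is a tibble with one row per animal and columns
#' `animal`, `sire`, `dam`, `birth_year` and `genotyped`. Unknown parents
#' are `NA`; animals with one or two unknown parents are treated as (partial)
#' founders of the base population. Validation checks id uniqueness, that
#' every known parent is itself a pedigree row, and that no known parent is
#' born in the same year as, or later than, its offspring.
#'
#' @param x A data frame with columns `animal`, `sire`, `dam`, `birth_year`,
#'   `genotyped` (`sire`/`dam` may use `NA`, `0` or `""` for unknown).
#' @return A validated tibble of class `ped_tbl`.
#' @export
#' @examples
#' ped_table(data.frame(
#'   animal = 1:3, sire = c(NA, NA, 1), dam = c(NA, NA, 2),
#'   birth_year = c(1, 1, 2), genotyped = c(FALSE, FALSE, TRUE)
#' ))
ped_table <- function(x) {
  required <- c("animal", "sire", "dam", "birth_year", "genotyped")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("pedigree is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  ped <- tibble::as_tibble(x)[required]
  ped$animal <- as.character(ped$animal)
  ped$sire <- normalize_parent(ped$sire)
  ped$dam <- normalize_parent(ped$dam)
  ped$birth_year <- as.integer(ped$birth_year)
  ped$genotyped <- as.logical(ped$genotyped)

  if (anyNA(ped$animal) || any(ped$animal == "")) {
    abort("animal ids must be non-missing")
  }
  dup <- ped$animal[duplicated(ped$animal)]
  if (length(dup) > 0) {
    abort(paste0("duplicated animal id(s): ", paste(head(unique(dup), 5), collapse = ", ")))
  }
  for (col in c("sire", "dam")) {
    known <- !is.na(ped[[col]])
    bad <- !(ped[[col]][known] %in% ped$animal)
    if (any(bad)) {
      abort(paste0("unknown ", col, " id(s): ",
                   paste(head(ped[[col]][known][bad], 5), collapse = ", ")))
    }
    self <- known & ped[[col]] == ped$animal
    if (any(self)) {
      abort(paste0("animal ", ped$animal[which(self)[1]], " is its own ", col,
                   " (pedigree cycle)"))
    }
  }
  if (anyNA(ped$birth_year)) abort("birth_year must be non-missing")
  if (anyNA(ped$genotyped)) abort("genotyped flag must be non-missing (0/1)")
  for (col in c("sire", "dam")) {
    idx <- match(ped[[col]], ped$animal)
    bad <- which(!is.na(idx) & ped$birth_year[idx] >= ped$birth_year)
    if (length(bad) > 0) {
      abort(paste0("animal ", ped$animal[bad[1]], " is not born after its ",
                   col, " (birth_year ", ped$birth_year[bad[1]], " vs ",
                   ped$birth_year[idx[bad[1]]], ")"))
    }
  }
  class(ped) <- c("ped_tbl", class(ped))
  ped
}

normalize_parent <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & (x == "0" | x == "")] <- NA_character_
  x
}

#' Parent row positions for a pedigree
#'
#' @param ped A `ped_tbl`.
#' @return List with integer vectors `sire` and `dam` of row positions
#'   (0 = unknown parent).
#' @keywords internal
ped_positions <- function(ped) {
  s <- match(ped$sire, ped$animal)
  d <- match(ped$dam, ped$animal)
  s[is.na(s)] <- 0L
  d[is.na(d)] <- 0L
  list(sire = as.integer(s), dam = as.integer(d))
}

#' Topologically sort a pedigree
#'
#' Reorders rows so that every known parent precedes its offspring. The
#' order is deterministic: animals are placed by pedigree depth (founders
#' first, then animals whose parents are all placed), with ties broken by
#' ascending animal id. A cycle (an animal among its own ancestors) is an
#' error naming one animal on the cycle.
#'
#' @param ped A `ped_tbl`.
#' @return The reordered `ped_tbl`.
#' @export
topo_sort_pedigree <- function(ped) {
  ped <- as_ped(ped)
  n <- nrow(ped)
  pos <- ped_positions(ped)
  indeg <- (pos$sire > 0L) + (pos$dam > 0L)

  children <- vector("list", n)
  for (col in pos) {
    has <- which(col > 0L)
    if (length(has) > 0) {
      spl <- split(has, col[has])
      for (nm in names(spl)) {
        p <- as.integer(nm)
        children[[p]] <- c(children[[p]], spl[[nm]])
      }
    }
  }

  level <- rep(NA_integer_, n)
  frontier <- which(indeg == 0L)
  lev <- 0L
  while (length(frontier) > 0) {
    level[frontier] <- lev
    kids <- unlist(children[frontier], use.names = FALSE)
    nxt <- integer(0)
    if (length(kids) > 0) {
      cnt <- table(kids)
      ids <- as.integer(names(cnt))
      indeg[ids] <- indeg[ids] - as.integer(cnt)
      nxt <- ids[indeg[ids] == 0L]
    }
    frontier <- nxt
    lev <- lev + 1L
  }
  if (anyNA(level)) {
    abort(paste0("pedigree cycle detected involving animal ",
                 ped$animal[which(is.na(level))[1]]))
  }
  ord <- order(level, ped$animal, method = "radix")
  out <- ped[ord, ]
  class(out) <- class(ped)
  out
}

as_ped <- function(ped) {
  if (inherits(ped, "ped_tbl")) ped else ped_table(ped)
}

is_topo_sorted <- function(ped) {
  pos <- ped_positions(ped)
  all(pos$sire < seq_len(nrow(ped))) && all(pos$dam < seq_len(nrow(ped)))
}

require_sorted <- function(ped) {
  ped <- as_ped(ped)
  if (!is_topo_sorted(ped)) ped <- topo_sort_pedigree(ped)
  ped
}

#' Inbreeding coefficients from a pedigree
#'
#' Computes per-animal inbreeding coefficients F by the Meuwissen-Luo
#' recursion on the topologically sorted pedigree. Animals with unknown
#' parents are treated as non-inbred base animals.
#'
#' @param ped A `ped_tbl` (sorted if needed).
#' @return A tibble with columns `animal` and `F`, in pedigree (sorted)
#'   order.
#' @export
compute_inbreeding <- function(ped) {
  ped <- require_sorted(ped)
  pos <- ped_positions(ped)
  f <- inbreeding_ml(pos$sire, pos$dam)
  tibble::tibble(animal = ped$animal, F = f)
}

#' Reduce a pedigree to genotyped animals and their ancestors
#'
#' Keeps exactly the genotyped target animals plus all of their pedigree
#' ancestors; animals that are neither targets nor ancestors of a target
#' are dropped. Parent links among retained animals are preserved, so
#' relationship coefficients among the retained animals are unchanged.
#'
#' @param ped A `ped_tbl`.
#' @param geno_ids Character vector of animal ids (defaults to the animals
#'   flagged `genotyped` in the pedigree).
#' @return The reduced `ped_tbl`, in the original row order.
#' @export
extract_reduced_pedigree <- function(ped, geno_ids = NULL) {
  ped <- as_ped(ped)
  if (is.null(geno_ids)) geno_ids <- ped$animal[ped$genotyped]
  geno_ids <- as.character(geno_ids)
  if (length(geno_ids) == 0) abort("geno_ids is empty: nothing to reduce to")
  bad <- setdiff(geno_ids, ped$animal)
  if (length(bad) > 0) {
    abort(paste0("geno_ids not in pedigree: ", paste(head(bad, 5), collapse = ", ")))
  }
  pos <- ped_positions(ped)
  keep <- ped$animal %in% geno_ids
  repeat {
    parents <- c(pos$sire[keep], pos$dam[keep])
    parents <- parents[parents > 0L]
    new <- parents[!keep[parents]]
    if (length(new) == 0) break
    keep[new] <- TRUE
  }
  out <- ped[keep, ]
  class(out) <- class(ped)
  out
}

#' Count genotyped offspring per genotyped animal
#'
#' Counts, for each genotyped animal, its direct offspring (as sire or dam)
#' that are themselves genotyped. This is the ranking statistic behind the
#' offspring-based core-group scenarios.
#'
#' @param ped A `ped_tbl`.
#' @return Tibble with columns `animal` and `n_genotyped_offspring`, one row
#'   per genotyped animal, in pedigree order.
#' @export
count_genotyped_offspring <- function(ped) {
  ped <- as_ped(ped)
  pos <- ped_positions(ped)
  kid_geno <- ped$genotyped
  counts <- numeric(nrow(ped))
  for (col in pos) {
    has <- col > 0L & kid_geno
    if (any(has)) {
      t <- tabulate(col[has], nbins = nrow(ped))
      counts <- counts + t
    }
  }
  tibble::tibble(
    animal = ped$animal[ped$genotyped],
    n_genotyped_offspring = as.integer(counts[ped$genotyped])
  )
}
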