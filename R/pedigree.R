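#' Construct a Pedigree
#'
#' @param records data.frame with columns `id`, `sire`, `dam`, `sex`,
#'   `birth_year`.  `"0"`, `""` and `NA` all denote an unknown parent.
#' @return a [Pedigree-class] object.
#' @examples
#' ped <- Pedigree(data.frame(
#'   id = c("s1", "d1", "o1"), sire = c(NA, NA, "s1"),
#'   dam = c(NA, NA, "d1"), sex = c("male", "female", "male"),
#'   birth_year = c(2000L, 2000L, 2005L)))
#' nIndividuals(ped)
#' @export
Pedigree <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (col in c("id", "sire", "dam")) {
    records[[col]] <- as.character(records[[col]])
    records[[col]][records[[col]] %in% c("0", "")] <- NA_character_
  }
  records$birth_year <- as.integer(records$birth_year)
  rownames(records) <- NULL
  new("Pedigree", records = records)
}

#' @rdname Pedigree
#' @export
setMethod("pedRecords", "Pedigree", function(x) x@records)

#' @rdname Pedigree
#' @param ped a Pedigree
#' @export
nIndividuals <- function(ped) nrow(ped@records)

#' @rdname Pedigree
#' @export
pedIds <- function(ped) ped@records$id

#' @rdname Pedigree
#' @export
founderIds <- function(ped) {
  df <- ped@records
  df$id[is.na(df$sire) & is.na(df$dam)]
}

setMethod("show", "Pedigree", function(object) {
  df <- object@records
  cat("Pedigree with", nrow(df), "individuals,",
      length(founderIds(object)), "founders, birth years",
      min(df$birth_year), "-", max(df$birth_year), "\n")
})

#' Paternal half-sib family membership
#'
#' Groups individuals by sire.  Individuals with an unknown sire each
#' form their own singleton family.
#'
#' @param ped a [Pedigree-class].
#' @param ids ids to group; default all.
#' @return named character vector: family label (sire id, or
#'   `"founder:<id>"`) per individual.
#' @export
halfSibFamilies <- function(ped, ids = pedIds(ped)) {
  df <- ped@records
  sire <- df$sire[match(ids, df$id)]
  fam <- ifelse(is.na(sire), paste0("founder:", ids), sire)
  names(fam) <- ids
  fam
}

# parents-before-offspring order (index vector); birth year is a valid
# topological key because validity enforces strict precedence
.pedOrder <- function(ped) order(ped@records$birth_year)

#' Simulate a multi-generation half-sib pedigree
#'
#' Emulates the family structure of a progeny-testing dairy population:
#' few heavily used sires produce large, right-skewed paternal half-sib
#' families; a fraction of matings repeat the same dam so full sibs
#' arise; selected sons of one generation become the sires of the next,
#' creating genotyped father/son chains.
#'
#' Half-sib family sizes are drawn as `1 + NegBin(mu = offspringPerSire
#' - 1, size = familySizeDispersion)`; with `familySizeDispersion = 0`
#' every family has exactly `offspringPerSire` members.
#'
#' @param nGenerations number of offspring generations after the founders.
#' @param foundersPerSex founder males and females (length-1 or -2).
#' @param siresPerGeneration sires sampled per generation among the
#'   previous generation's males.
#' @param offspringPerSire mean half-sib family size.
#' @param fullSibRate probability that an offspring repeats an earlier
#'   (sire, dam) mating, producing a full sib.
#' @param familySizeDispersion negative-binomial size parameter for the
#'   family-size distribution (small = heavy right tail; 0 = fixed size).
#' @param seed RNG seed.
#' @return a [Pedigree-class].
#' @examples
#' ped <- simulatePedigree(2, c(5, 40), 4, 6, seed = 1)
#' table(pedRecords(ped)$birth_year)
#' @export
simulatePedigree <- function(nGenerations, foundersPerSex,
                             siresPerGeneration, offspringPerSire,
                             fullSibRate = 0.05,
                             familySizeDispersion = 0.35,
                             seed = NULL) {
  stopifnot(nGenerations >= 1, all(foundersPerSex >= 1),
            siresPerGeneration >= 1, offspringPerSire >= 1,
            fullSibRate >= 0, fullSibRate < 1)
  if (length(foundersPerSex) == 1L) foundersPerSex <- rep(foundersPerSex, 2L)
  run <- function() {
    y0 <- 1980L
    nm <- foundersPerSex[1]; nf <- foundersPerSex[2]
    males <- sprintf("M0_%d", seq_len(nm))
    females <- sprintf("F0_%d", seq_len(nf))
    rec <- data.frame(
      id = c(males, females),
      sire = NA_character_, dam = NA_character_,
      sex = rep(c("male", "female"), c(nm, nf)),
      birth_year = y0, stringsAsFactors = FALSE)
    prevM <- males; prevF <- females
    for (g in seq_len(nGenerations)) {
      yr <- y0 + 5L * g
      nsire <- min(siresPerGeneration, length(prevM))
      sires <- sample(prevM, nsire)
      if (familySizeDispersion > 0) {
        fsz <- 1L + stats::rnbinom(nsire, size = familySizeDispersion,
                                   mu = offspringPerSire - 1)
      } else fsz <- rep(as.integer(offspringPerSire), nsire)
      gid <- 0L
      gm <- character(); gf <- character()
      grec <- vector("list", nsire)
      for (s in seq_len(nsire)) {
        m <- fsz[s]
        # distinct dams for the non-repeat matings of this sire
        nFull <- if (m > 1) stats::rbinom(1L, m - 1L, fullSibRate) else 0L
        nDams <- m - nFull
        if (nDams > length(prevF))
          stop("sizing error: sire family of ", m, " offspring demands ",
               nDams, " dams but only ", length(prevF), " are available")
        dams <- sample(prevF, nDams)
        damSeq <- c(dams, sample(dams, nFull, replace = TRUE))
        sexSeq <- sample(c("male", "female"), m, replace = TRUE)
        ids <- sprintf("G%d_%d", g, gid + seq_len(m)); gid <- gid + m
        grec[[s]] <- data.frame(id = ids, sire = sires[s], dam = damSeq,
                                sex = sexSeq, birth_year = yr,
                                stringsAsFactors = FALSE)
        gm <- c(gm, ids[sexSeq == "male"])
        gf <- c(gf, ids[sexSeq == "female"])
      }
      rec <- rbind(rec, do.call(rbind, grec))
      prevM <- gm
      # dams can be reused across generations in cattle; carry females over
      prevF <- c(gf, prevF)
      if (length(prevM) == 0L && g < nGenerations)
        stop("sizing error: no male offspring available to sire generation ",
             g + 1L)
    }
    Pedigree(rec)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
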