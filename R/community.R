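#' Construct a community count matrix
#'
#' Builds the core container for trap-by-year-by-species count data: a
#' three-dimensional integer array indexed by trap, successional year and
#' species. Absent combinations are explicit zeros; every (trap, year) cell of
#' the trapping design is represented, so "species not caught" is
#' distinguishable from "trap not operated".
#'
#' @param trap,year,species,count parallel vectors giving one observation per
#'   element. `year` may be calendar years; they are recoded internally to
#'   successional years `1..T` in increasing order (the original labels are
#'   kept in the `year_levels` attribute).
#' @param traps,years,species_pool optional supersets fixing the design; rows
#'   not listed are an error, listed levels absent from the data become
#'   all-zero slices.
#' @return An object of class `community_matrix`: an integer array with
#'   dimensions (trap, year, species) and dimnames, plus a `year_levels`
#'   attribute mapping successional years back to the input labels.
#' @examples
#' m <- community_matrix(
#'   trap = c("t1", "t1", "t1"), year = c(1, 2, 2),
#'   species = c("spA", "spA", "spB"), count = c(2, 0, 5)
#' )
#' total_abundance(m) # 7
#' @export
community_matrix <- function(trap, year, species, count,
                             traps = NULL, years = NULL, species_pool = NULL) {
  n <- length(trap)
  if (length(year) != n || length(species) != n || length(count) != n)
    stop("trap, year, species and count must have equal length")
  year_num <- suppressWarnings(as.numeric(as.character(year)))
  if (anyNA(year_num))
    stop("years must be coercible to numbers; offending values: ",
         paste(utils::head(unique(year[is.na(year_num)]), 5), collapse = ", "))
  if (any(year_num != round(year_num)))
    stop("years must be integral")
  count_num <- suppressWarnings(as.numeric(count))
  bad <- which(is.na(count_num) | count_num < 0 | count_num != round(count_num))
  if (length(bad))
    stop("counts must be non-negative integers; offending rows: ",
         paste(utils::head(bad, 5), collapse = ", "))

  trap <- as.character(trap)
  species <- as.character(species)
  year_lv <- if (is.null(years)) sort(unique(year_num)) else sort(unique(as.numeric(years)))
  if (!all(year_num %in% year_lv)) stop("year outside the declared design years")
  trap_lv <- if (is.null(traps)) sort(unique(trap)) else as.character(traps)
  if (!all(trap %in% trap_lv)) stop("trap outside the declared trap set")
  sp_lv <- if (is.null(species_pool)) sort(unique(species)) else as.character(species_pool)
  if (!all(species %in% sp_lv)) stop("species outside the declared species pool")

  key <- paste(trap, year_num, species, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))
    stop("duplicate (trap, year, species) keys at rows: ",
         paste(utils::head(dup, 5), collapse = ", "),
         " (duplicates are an error, not summed)")
  }

  arr <- array(0L, dim = c(length(trap_lv), length(year_lv), length(sp_lv)),
               dimnames = list(trap = trap_lv,
                               year = as.character(seq_along(year_lv)),
                               species = sp_lv))
  idx <- cbind(match(trap, trap_lv), match(year_num, year_lv), match(species, sp_lv))
  arr[idx] <- as.integer(count_num)
  structure(arr, year_levels = year_lv, class = "community_matrix")
}

#' @export
print.community_matrix <- function(x, ...) {
  d <- dim(x)
  cat("Community matrix:", d[1], "traps x", d[2], "years x", d[3], "species\n")
  cat("Total individuals:", sum(x), "\n")
  yl <- attr(x, "year_levels")
  if (!identical(as.numeric(yl), as.numeric(seq_along(yl))))
    cat("Successional years 1..", d[2], " recode calendar years ",
        paste(yl, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.community_matrix <- function(object, ...) {
  occ <- apply(object > 0, 3, sum)
  out <- list(dim = dim(object), total = sum(object),
              species_occupancy = summary(occ),
              empty_samples = sum(apply(object, c(1, 2), sum) == 0))
  class(out) <- "summary.community_matrix"
  out
}

#' @export
print.summary.community_matrix <- function(x, ...) {
  cat("Community matrix:", x$dim[1], "traps x", x$dim[2], "years x",
      x$dim[3], "species;", x$total, "individuals\n")
  cat("Empty (trap, year) samples:", x$empty_samples, "\n")
  cat("Species occupancy (trap-years with count > 0):\n")
  print(x$species_occupancy)
  invisible(x)
}

#' Accessors for community matrices
#'
#' @param x a `community_matrix`.
#' @return `traps()`, `study_years()` and `species_ids()` return character or
#'   integer vectors of design levels; `total_abundance()` the summed count.
#' @export
traps <- function(x) dimnames(x)$trap

#' @rdname traps
#' @export
study_years <- function(x) as.integer(dimnames(x)$year)

#' @rdname traps
#' @export
species_ids <- function(x) dimnames(x)$species

#' @rdname traps
#' @export
total_abundance <- function(x) sum(x)

default_dialect <- function() {
  list(trap = "trap", year = "year", species = "species", count = "count")
}

#' Read a long-format community table from CSV
#'
#' The canonical input is a long (tidy) CSV with one row per observed
#' (trap, year, species) combination. Missing combinations are implicit zeros
#' for species, but every (trap, year) sample in the design must appear at
#' least once (a zero-count row suffices for empty samples). Wide
#' species-by-sample matrices are supported with `wide = TRUE`, where the
#' first two columns are trap and year and the remaining columns are species.
#'
#' @param path CSV file path (UTF-8, header row required).
#' @param dialect named list remapping the column names `trap`, `year`,
#'   `species`, `count`.
#' @param wide logical; read a wide species-by-sample matrix instead.
#' @inheritParams community_matrix
#' @return a [community_matrix()].
#' @export
read_community <- function(path, dialect = default_dialect(), wide = FALSE,
                           traps = NULL, years = NULL, species_pool = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (wide) {
    if (ncol(df) < 3) stop("wide format needs trap, year and >=1 species column")
    long <- data.frame(
      trap = rep(df[[1]], ncol(df) - 2L),
      year = rep(df[[2]], ncol(df) - 2L),
      species = rep(colnames(df)[-(1:2)], each = nrow(df)),
      count = unlist(df[-(1:2)], use.names = FALSE)
    )
    return(community_matrix(long$trap, long$year, long$species, long$count,
                            traps = traps, years = years,
                            species_pool = species_pool))
  }
  need <- unlist(dialect[c("trap", "year", "species", "count")])
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("column(s) not found in ", path, ": ", paste(miss, collapse = ", "))
  community_matrix(df[[dialect$trap]], df[[dialect$year]],
                   df[[dialect$species]], df[[dialect$count]],
                   traps = traps, years = years, species_pool = species_pool)
}

#' Write a community matrix to long-format CSV
#'
#' With `sparse = TRUE` only nonzero counts are written, plus one zero-count
#' placeholder row per empty (trap, year) sample so the design is preserved on
#' re-read; species never observed anywhere are then dropped. `sparse = FALSE`
#' writes the complete grid and round-trips exactly.
#'
#' @param x a `community_matrix`.
#' @param path output CSV path.
#' @param sparse write only nonzero rows (plus design placeholders)?
#' @return `path`, invisibly.
#' @export
write_community <- function(x, path, sparse = FALSE) {
  yl <- attr(x, "year_levels")
  long <- data.frame(
    trap = rep(traps(x), times = dim(x)[2] * dim(x)[3]),
    year = rep(rep(yl, each = dim(x)[1]), times = dim(x)[3]),
    species = rep(species_ids(x), each = dim(x)[1] * dim(x)[2]),
    count = as.integer(x)
  )
  if (sparse) {
    keep <- long$count > 0
    sample_key <- paste(long$trap, long$year)
    covered <- unique(sample_key[keep])
    placeholder <- !duplicated(sample_key) & !(sample_key %in% covered)
    long <- long[keep | placeholder, ]
  }
  long <- long[order(long$trap, long$year, long$species), ]
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a species trait table
#'
#' @param path CSV with columns `species`, `host_affinity`
#'   (specialist / generalist / non_aspen) and `guild` (wood_feeder /
#'   fungivore / predator / omnivore_saprophage / unassigned).
#' @return a `trait_table` data frame.
#' @export
read_traits <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  trait_table(df$species, df$host_affinity, df$guild)
}

#' @rdname read_traits
#' @param species,host_affinity,guild parallel vectors for in-memory
#'   construction.
#' @export
trait_table <- function(species, host_affinity, guild = NULL) {
  affin_lv <- c("specialist", "generalist", "non_aspen")
  guild_lv <- c("wood_feeder", "fungivore", "predator", "omnivore_saprophage",
                "unassigned")
  species <- as.character(species)
  if (anyDuplicated(species))
    stop("duplicate species in trait table (guild membership is single): ",
         paste(utils::head(species[duplicated(species)], 5), collapse = ", "))
  if (!all(host_affinity %in% affin_lv))
    stop("host_affinity must be one of: ", paste(affin_lv, collapse = ", "))
  if (is.null(guild)) guild <- rep("unassigned", length(species))
  if (!all(guild %in% guild_lv))
    stop("guild must be one of: ", paste(guild_lv, collapse = ", "))
  aspen <- host_affinity %in% c("specialist", "generalist")
  if (any(aspen & guild == "unassigned"))
    stop("aspen-associated species must have a guild: ",
         paste(utils::head(species[aspen & guild == "unassigned"], 5),
               collapse = ", "))
  structure(data.frame(species = species, host_affinity = host_affinity,
                       guild = guild, stringsAsFactors = FALSE),
            class = c("trait_table", "data.frame"))
}

#' Read and validate the trap (site) table
#'
#' @param path CSV with columns `trap`, `environment` (exposed / shaded),
#'   `landscape`, and optionally `fungal_diversity` (non-negative integer
#'   count of fungal and slime-mold taxa on the stump; may be missing).
#' @return a `site_table` data frame.
#' @export
read_sites <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  fd <- if ("fungal_diversity" %in% names(df)) df$fungal_diversity else NULL
  site_table(df$trap, df$environment, df$landscape, fd)
}

#' @rdname read_sites
#' @param trap,environment,landscape,fungal_diversity parallel vectors for
#'   in-memory construction.
#' @export
site_table <- function(trap, environment, landscape, fungal_diversity = NULL) {
  trap <- as.character(trap)
  if (anyDuplicated(trap))
    stop("duplicate traps in site table: ",
         paste(utils::head(trap[duplicated(trap)], 5), collapse = ", "))
  if (!all(environment %in% c("exposed", "shaded")))
    stop("environment must be 'exposed' or 'shaded'")
  if (anyNA(environment) || anyNA(landscape))
    stop("environment and landscape must be non-missing")
  if (is.null(fungal_diversity)) fungal_diversity <- rep(NA_integer_, length(trap))
  ok <- is.na(fungal_diversity) |
    (fungal_diversity >= 0 & fungal_diversity == round(fungal_diversity))
  if (!all(ok)) stop("fungal_diversity must be a non-negative integer or NA")
  structure(data.frame(trap = trap, environment = as.character(environment),
                       landscape = as.character(landscape),
                       fungal_diversity = as.integer(fungal_diversity),
                       stringsAsFactors = FALSE),
            class = c("site_table", "data.frame"))
}

check_traits_cover <- function(x, traits) {
  miss <- setdiff(species_ids(x), traits$species)
  if (length(miss))
    stop("species missing from trait table: ", paste(miss, collapse = ", "))
}

#' Drop species not associated with the host tree
#'
#' Retains only species whose host affinity is `specialist` or `generalist`;
#' species classified `non_aspen` are excluded from all downstream analyses.
#' Counts of retained species are unchanged and the trap/year design is
#' preserved. The operation is idempotent.
#'
#' @param x a [community_matrix()].
#' @param traits a [trait_table()] covering every species in `x`.
#' @return a `community_matrix` restricted to host-associated species.
#' @export
filter_aspen <- function(x, traits) {
  check_traits_cover(x, traits)
  affin <- traits$host_affinity[match(species_ids(x), traits$species)]
  keep <- affin %in% c("specialist", "generalist")
  out <- x[, , keep, drop = FALSE]
  structure(out, year_levels = attr(x, "year_levels"), class = "community_matrix")
}

group_species <- function(traits, group) {
  group <- match.arg(group, c("all", "specialist", "generalist", "wood_feeder",
                              "fungivore", "predator", "omnivore_saprophage"))
  if (group == "all") traits$species[traits$host_affinity != "non_aspen"]
  else if (group %in% c("specialist", "generalist"))
    traits$species[traits$host_affinity == group]
  else traits$species[traits$guild == group &
                      traits$host_affinity != "non_aspen"]
}

#' Aggregate a community matrix to a functional-group series
#'
#' Computes, per (trap, year) sample, the species richness (number of species
#' in the group with count > 0) and abundance (summed individuals) for one
#' functional group: a host-affinity class, a trophic guild, or all
#' host-associated species.
#'
#' @param x an aspen-filtered [community_matrix()].
#' @param traits a [trait_table()].
#' @param group one of `"all"`, `"specialist"`, `"generalist"`,
#'   `"wood_feeder"`, `"fungivore"`, `"predator"`, `"omnivore_saprophage"`.
#' @return a `group_series` data frame with columns trap, year, richness,
#'   abundance, and the group name in attribute `group`.
#' @export
aggregate_group <- function(x, traits, group = "all") {
  check_traits_cover(x, traits)
  sel <- intersect(species_ids(x), group_species(traits, group))
  if (group != "all" && !length(group_species(traits, group)))
    stop("empty group selector: no species classified as ", group)
  sub <- x[, , sel, drop = FALSE]
  rich <- apply(sub > 0, c(1, 2), sum)
  abun <- apply(sub, c(1, 2), sum)
  out <- data.frame(
    trap = rep(traps(x), times = dim(x)[2]),
    year = rep(study_years(x), each = dim(x)[1]),
    richness = as.integer(rich),
    abundance = as.integer(abun)
  )
  structure(out, group = group, class = c("group_series", "data.frame"))
}
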