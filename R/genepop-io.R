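#' Read a Genepop file into a genotype dataset
#'
#' Parses the classic Genepop dialect: a title line, one locus name per line
#' (a single comma-separated line is also accepted), population blocks opened
#' by a line reading `POP` (case-insensitive), and individual lines of the
#' form `label , 0101 0102 ...` with 2- or 3-digit allele codes (`00` /
#' `000` = missing). Genotypes are recoded to counts of the *counted* allele,
#' defined as the numerically smaller allele code observed at each locus, so
#' the coding is deterministic and independent of file order. A genotype with
#' any missing allele is treated as missing.
#'
#' The population label defaults to the substring of the block's first
#' individual label before the last underscore (Genepop has no population
#' name field); coordinates and lineage are joined from `metadata`.
#'
#' @param path Path to the Genepop file.
#' @param metadata Population metadata: a data frame with columns
#'   `population,latitude,longitude,lineage`, or the path of a CSV with that
#'   header.
#' @return A [genotype_dataset()].
#' @seealso [write_genepop()], [read_genotype_csv()]
#' @export
read_genepop <- function(path, metadata) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\s+$", "", lines)
  if (length(lines) < 3) stop("Genepop parse error: file too short")
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop) || first_pop < 3)
    stop("Genepop parse error: no POP delimiter after locus list")

  locus_lines <- trimws(lines[2:(first_pop - 1)])
  locus_lines <- locus_lines[nzchar(locus_lines)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  if (!length(loci)) stop("Genepop parse error: empty locus list (line 2)")
  if (anyDuplicated(loci))
    stop("Genepop parse error: duplicate locus names in header")

  pop_starts <- which(is_pop)
  ind_label <- character(0); ind_pop_idx <- integer(0)
  allele_rows <- list()
  width <- NA_integer_

  for (b in seq_along(pop_starts)) {
    from <- pop_starts[b] + 1L
    to <- if (b < length(pop_starts)) pop_starts[b + 1L] - 1L else length(lines)
    block <- from:to
    block <- block[nzchar(trimws(lines[block]))]
    if (!length(block))
      stop("Genepop parse error: empty POP block at line ", pop_starts[b])
    for (ln in block) {
      txt <- lines[ln]
      comma <- regexpr(",", txt, fixed = TRUE)
      if (comma < 0)
        stop("Genepop parse error: no comma-terminated label at line ", ln)
      label <- trimws(substr(txt, 1, comma - 1))
      gens <- strsplit(trimws(substr(txt, comma + 1, nchar(txt))), "\\s+")[[1]]
      if (length(gens) != length(loci))
        stop("Genepop parse error: expected ", length(loci),
             " genotypes, found ", length(gens), " at line ", ln)
      w <- unique(nchar(gens))
      if (length(w) != 1 || !(w %in% c(4L, 6L)))
        stop("Genepop parse error: genotype fields must be 4 or 6 digits at line ", ln)
      if (is.na(width)) width <- w / 2L
      else if (width != w / 2L)
        stop("Genepop parse error: inconsistent allele-code width at line ", ln)
      a1 <- as.integer(substr(gens, 1L, width))
      a2 <- as.integer(substr(gens, width + 1L, 2L * width))
      if (anyNA(a1) || anyNA(a2))
        stop("Genepop parse error: non-numeric genotype at line ", ln)
      ind_label <- c(ind_label, label)
      ind_pop_idx <- c(ind_pop_idx, b)
      allele_rows[[length(allele_rows) + 1L]] <- rbind(a1, a2)
    }
  }

  n_ind <- length(ind_label)
  a1 <- t(vapply(allele_rows, function(m) m[1, ], integer(length(loci))))
  a2 <- t(vapply(allele_rows, function(m) m[2, ], integer(length(loci))))
  if (length(loci) == 1L) { a1 <- matrix(a1, ncol = 1); a2 <- matrix(a2, ncol = 1) }
  a1[a1 == 0L] <- NA_integer_; a2[a2 == 0L] <- NA_integer_
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA_integer_; a2[miss] <- NA_integer_

  geno <- matrix(NA_integer_, n_ind, length(loci),
                 dimnames = list(ind_label, loci))
  for (j in seq_along(loci)) {
    alleles <- sort(unique(c(a1[, j], a2[, j])))
    alleles <- alleles[!is.na(alleles)]
    if (length(alleles) > 2L)
      stop("biallelic violation: locus ", loci[j], " has ",
           length(alleles), " alleles (", paste(alleles, collapse = ","), ")")
    counted <- if (length(alleles)) min(alleles) else NA_integer_
    if (!is.na(counted))
      geno[, j] <- (a1[, j] == counted) + (a2[, j] == counted)
  }

  pop_names <- vapply(pop_starts, function(i) "", character(1))
  first_of_block <- ind_label[match(seq_along(pop_starts), ind_pop_idx)]
  pop_names <- sub("_[^_]*$", "", first_of_block)

  meta <- read_population_metadata(metadata)
  unknown <- setdiff(pop_names, meta$population)
  if (length(unknown))
    stop("missing metadata for populations: ", paste(unknown, collapse = ", "))

  individuals <- data.frame(individual = ind_label,
                            population = pop_names[ind_pop_idx],
                            stringsAsFactors = FALSE)
  genotype_dataset(geno, individuals,
                   meta[meta$population %in% pop_names, , drop = FALSE])
}

#' Write a genotype dataset as a Genepop file
#'
#' Counted-allele codes map back to allele pairs `01`/`02` (2-digit dialect):
#' code 2 becomes `0101`, 1 becomes `0102`, 0 becomes `0202`, missing `0000`.
#' Individual labels are written as `population_suffix` so [read_genepop()]
#' recovers the population; an id already prefixed with its population name
#' is written unchanged.
#'
#' @param ds A [genotype_dataset()].
#' @param path Output path.
#' @param title Title line content.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(ds, path, title = "latcline export") {
  stopifnot(inherits(ds, "genotype_dataset"))
  loci <- colnames(ds$genotypes)
  codes <- c(`0` = "0202", `1` = "0102", `2` = "0101")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(title, loci), con)
  for (pop in unique(ds$individuals$population)) {
    writeLines("POP", con)
    idx <- which(ds$individuals$population == pop)
    for (i in idx) {
      id <- ds$individuals$individual[i]
      label <- if (startsWith(id, paste0(pop, "_"))) id else paste0(pop, "_", id)
      g <- ds$genotypes[i, ]
      field <- ifelse(is.na(g), "0000", codes[as.character(g)])
      writeLines(paste0(label, " ,  ", paste(field, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read or validate a population metadata table
#'
#' @param metadata A data frame or CSV path with header
#'   `population,latitude,longitude,lineage`.
#' @return A validated data frame.
#' @export
read_population_metadata <- function(metadata) {
  if (is.character(metadata))
    metadata <- utils::read.csv(metadata, stringsAsFactors = FALSE)
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  need <- c("population", "latitude", "longitude", "lineage")
  if (!all(need %in% names(metadata)))
    stop("population metadata needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(metadata$population))
    stop("duplicate population ids in metadata")
  metadata[, need]
}

#' Read / write the plain genotype CSV dialect
#'
#' One row per individual: columns `individual`, `population`, then one
#' column per locus holding 0/1/2/NA counted-allele codes.
#'
#' @param path CSV path.
#' @param metadata Population metadata (see [read_population_metadata()]).
#' @return A [genotype_dataset()] for the reader; `path` for the writer.
#' @export
read_genotype_csv <- function(path, metadata) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("individual", "population") %in% names(df)))
    stop("genotype CSV needs leading columns `individual,population`")
  loci <- setdiff(names(df), c("individual", "population"))
  if (!length(loci)) stop("genotype CSV has no locus columns")
  geno <- as.matrix(df[, loci, drop = FALSE])
  storage.mode(geno) <- "integer"
  meta <- read_population_metadata(metadata)
  genotype_dataset(geno, df[, c("individual", "population")],
                   meta[meta$population %in% df$population, , drop = FALSE])
}

#' @rdname read_genotype_csv
#' @param ds A [genotype_dataset()] to write.
#' @export
write_genotype_csv <- function(ds, path) {
  stopifnot(inherits(ds, "genotype_dataset"))
  df <- cbind(ds$individuals, as.data.frame(ds$genotypes, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}
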