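#' Write a sample in Genepop format
#'
#' Four-digit allele coding.  Allele IDs that fit in four digits (max 9998)
#' are written as-is; otherwise each locus's alleles are recoded to dense
#' ranks and the mapping is written to a sidecar file
#' `<path>.alleles.csv` (columns `locus`, `code`, `allele_id`), which
#' [read_genepop()] uses to restore the original IDs.
#'
#' @param sample A `sample_set`.
#' @param path Output file.
#' @param pop_by `"quadrant"` (one POP per true quadrant) or `"single"`.
#' @param title Header line content.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(sample, path, pop_by = c("quadrant", "single"),
                          title = NULL) {
  pop_by <- match.arg(pop_by)
  stopifnot(inherits(sample, "sample_set"))
  L <- sample$n_loci
  geno <- sample$genotypes
  remap <- max(geno) > 9998L
  map_rows <- NULL
  if (remap) {
    for (l in seq_len(L)) {
      cols <- c(2 * l - 1, 2 * l)
      ids <- sort(unique(as.vector(geno[, cols])))
      if (length(ids) > 9998L)
        stop("locus ", l, " has more than 9998 alleles; cannot encode",
             call. = FALSE)
      geno[, cols] <- match(geno[, cols], ids)
      map_rows[[l]] <- data.frame(locus = l, code = seq_along(ids),
                                  allele_id = ids)
    }
  }
  if (any(geno < 0L) || any(geno > 9998L))
    stop("allele codes outside the 4-digit Genepop range", call. = FALSE)
  # Genepop codes are 1-based; raw simulator IDs start at 0
  offset <- if (remap) 0L else 1L
  codes <- matrix(sprintf("%04d", geno + offset), nrow = nrow(geno))
  lines <- c(
    if (is.null(title))
      sprintf("barrierbench export: generation %d, replicate %d%s",
              sample$generation, sample$replicate_id,
              if (remap) " (allele IDs remapped, see sidecar)" else "")
    else title,
    paste0("locus", seq_len(L)))
  grp <- if (pop_by == "quadrant") sample$coords$quadrant else
    rep(0L, nrow(geno))
  for (g in sort(unique(grp))) {
    lines <- c(lines, "POP")
    rows <- which(grp == g)
    gl <- vapply(rows, function(i) {
      fields <- paste0(codes[i, seq(1, 2 * L, by = 2)],
                       codes[i, seq(2, 2 * L, by = 2)])
      paste0("ind", sample$coords$id[i], " ,  ",
             paste(fields, collapse = " "))
    }, character(1))
    lines <- c(lines, gl)
  }
  writeLines(lines, path)
  if (remap)
    write.csv(do.call(rbind, map_rows), paste0(path, ".alleles.csv"),
              row.names = FALSE)
  invisible(path)
}

#' Read a Genepop file
#'
#' Supports the 4-digit diploid coding written by [write_genepop()] (one
#' locus name per line).  If a sidecar allele map is present, original
#' allele IDs are restored.
#'
#' @param path Genepop file.
#' @return A list: `genotypes` (n x 2L integer matrix), `n_loci`, `pop`
#'   (integer group index per individual), `ids` (individual names).
#' @export
read_genepop <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("malformed Genepop file: too short",
                              call. = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("malformed Genepop file: no POP line",
                             call. = FALSE)
  L <- first_pop - 2L
  if (L < 1) stop("malformed Genepop file: no loci", call. = FALSE)
  pop_idx <- cumsum(is_pop)
  rows <- which(!is_pop & seq_along(lines) > first_pop - 1L)
  ids <- character(0); pops <- integer(0); geno <- NULL
  gmat <- matrix(NA_integer_, length(rows), 2L * L)
  for (k in seq_along(rows)) {
    ln <- lines[rows[k]]
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2)
      stop("malformed Genepop genotype line ", rows[k], ": ", ln,
           call. = FALSE)
    ids <- c(ids, trimws(parts[1]))
    fields <- strsplit(trimws(paste(parts[-1], collapse = ",")),
                       "[[:space:]]+")[[1]]
    if (length(fields) != L)
      stop("line ", rows[k], ": expected ", L, " loci, found ",
           length(fields), call. = FALSE)
    if (any(nchar(fields) != 8))
      stop("line ", rows[k], ": expected 8-digit diploid fields",
           call. = FALSE)
    a1 <- as.integer(substr(fields, 1, 4))
    a2 <- as.integer(substr(fields, 5, 8))
    gmat[k, seq(1, 2 * L, 2)] <- a1
    gmat[k, seq(2, 2 * L, 2)] <- a2
    pops <- c(pops, pop_idx[rows[k]])
  }
  sidecar <- paste0(path, ".alleles.csv")
  if (file.exists(sidecar)) {
    map <- read.csv(sidecar)
    for (l in seq_len(L)) {
      m <- map[map$locus == l, ]
      cols <- c(2 * l - 1, 2 * l)
      gmat[, cols] <- m$allele_id[match(gmat[, cols], m$code)]
    }
  } else {
    gmat <- gmat - 1L   # undo the 1-based Genepop offset
  }
  colnames(gmat) <- paste0("L", rep(seq_len(L), each = 2), ".", rep(1:2, L))
  list(genotypes = gmat, n_loci = L, pop = pops, ids = ids)
}

#' Write a sample in STRUCTURE two-row format
#'
#' Two rows per individual (one allele per row), columns: individual ID,
#' then one column per locus; missing data coded `-9` (the simulator never
#' produces missing genotypes, but external data may).
#'
#' @param sample A `sample_set`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(sample, path) {
  stopifnot(inherits(sample, "sample_set"))
  L <- sample$n_loci
  geno <- sample$genotypes
  geno[is.na(geno)] <- -9L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(paste0("locus", seq_len(L)), collapse = "\t"), con)
  for (i in seq_len(nrow(geno))) {
    for (a in 1:2)
      writeLines(paste(c(paste0("ind", sample$coords$id[i]),
                         geno[i, seq(a, 2 * L, by = 2)]),
                       collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a STRUCTURE two-row file
#'
#' @param path File written by [write_structure()] (header of locus names,
#'   then two rows per individual).
#' @return A list: `genotypes`, `n_loci`, `ids`.
#' @export
read_structure <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]
  L <- length(header)
  body <- lines[-1]
  if (length(body) %% 2 != 0)
    stop("malformed STRUCTURE file: odd number of genotype rows",
         call. = FALSE)
  n <- length(body) %/% 2
  gmat <- matrix(NA_integer_, n, 2L * L)
  ids <- character(n)
  for (i in seq_len(n)) {
    for (a in 1:2) {
      ln <- body[2 * (i - 1) + a]
      fields <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
      if (length(fields) != L + 1)
        stop("malformed STRUCTURE line ", 1 + 2 * (i - 1) + a, ": ", ln,
             call. = FALSE)
      if (a == 1) ids[i] <- fields[1]
      else if (fields[1] != ids[i])
        stop("STRUCTURE rows ", 2 * i, "-", 2 * i + 1,
             ": individual IDs disagree", call. = FALSE)
      gmat[i, seq(a, 2 * L, by = 2)] <- as.integer(fields[-1])
    }
  }
  gmat[gmat == -9L] <- NA_integer_
  colnames(gmat) <- paste0("L", rep(seq_len(L), each = 2), ".", rep(1:2, L))
  list(genotypes = gmat, n_loci = L, ids = ids)
}

#' Read a cluster-membership (Q-matrix) file
#'
#' Accepts either a two-column hard-assignment CSV (`id`, `cluster`) or a
#' CLUMPP/STRUCTURE-style Q-matrix whose rows end in `K` membership
#' coefficients (an optional `:` separates the leading columns from the
#' coefficients).  Coefficient rows not summing to approximately 1 are
#' renormalized with a warning; hard assignments are taken by argmax with
#' ties broken towards the lower cluster index.
#'
#' @param path Membership file.
#' @param source Method label stored in the result.
#' @return A `cluster_result`.
#' @export
read_qmatrix <- function(path, source = NULL) {
  if (is.null(source))
    source <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (grepl(",", lines[min(2, length(lines))], fixed = TRUE) &&
      !grepl(":", lines[min(2, length(lines))], fixed = TRUE)) {
    df <- read.csv(path, header = grepl("[A-Za-z]", lines[1]))
    if (ncol(df) == 2) {
      m <- as.integer(factor(df[[2]]))
      return(cluster_result(max(m), m, source))
    }
    qm <- as.matrix(df[, -1, drop = FALSE])
  } else {
    qm <- t(vapply(lines, function(ln) {
      if (grepl(":", ln, fixed = TRUE))
        ln <- sub("^.*:", "", ln)
      as.numeric(strsplit(trimws(ln), "[[:space:],]+")[[1]])
    }, numeric(length(strsplit(trimws(sub("^.*:", "",
                                          lines[1])),
                               "[[:space:],]+")[[1]]))))
    rownames(qm) <- NULL
    # drop leading non-coefficient columns (id, %miss) when the rows do not
    # sum to ~1 but a trailing block does
    while (ncol(qm) > 1 &&
           max(abs(rowSums(qm) - 1)) > 0.05 &&
           max(abs(rowSums(qm[, -1, drop = FALSE]) - 1)) <= 0.05)
      qm <- qm[, -1, drop = FALSE]
  }
  if (any(is.na(qm))) stop("could not parse Q-matrix ", path, call. = FALSE)
  rs <- rowSums(qm)
  if (max(abs(rs - 1)) > 0.02) {
    warning("Q-matrix rows do not sum to 1; renormalizing", call. = FALSE)
    qm <- qm / rs
  }
  m <- apply(qm, 1, which.max)   # which.max breaks ties towards lower index
  cluster_result(ncol(qm), m, source)
}

#' Write / read sample coordinates
#'
#' CSV with columns `id`, `x`, `y`, `quadrant`.  Coordinates are 0-based
#' cells, `x` the column and `y` the row, cell centres at integers (a
#' comment line in the file records this convention).
#'
#' @param sample A `sample_set`.
#' @param path CSV file.
#' @return `path` (writer) or the coordinates data.frame (reader).
#' @export
write_coords <- function(sample, path) {
  stopifnot(inherits(sample, "sample_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# 0-based cells; x = column, y = row; cell centres at integers",
             con)
  write.csv(sample$coords, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_coords
#' @export
read_coords <- function(path) {
  read.csv(path, comment.char = "#")
}

#' Read / write an experiment configuration
#'
#' YAML round-trip of the benchmark configuration consumed by
#' [run_benchmark()] and the command-line front end.
#'
#' @param path YAML file.
#' @param config Configuration list.
#' @return The configuration list (reader) or `path` (writer).
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Export a replicate's samples to disk
#'
#' Writes, for every export generation, a Genepop file, a STRUCTURE file
#' and a coordinates CSV, named
#' `<basename>_gen<g>.{gen,str,coords.csv}`.
#'
#' @param samples List of `sample_set` objects (one replicate's time
#'   points).
#' @param dir Output directory (created if needed).
#' @param basename File-name prefix.
#' @return Character vector of written paths, invisibly.
#' @export
export_replicate <- function(samples, dir, basename = "sample") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (s in samples) {
    stem <- file.path(dir, sprintf("%s_gen%d", basename, s$generation))
    paths <- c(paths,
               write_genepop(s, paste0(stem, ".gen")),
               write_structure(s, paste0(stem, ".str")),
               write_coords(s, paste0(stem, ".coords.csv")))
  }
  invisible(paths)
}
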