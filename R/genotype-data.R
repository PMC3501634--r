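#' Describe a microsatellite locus
#'
#' A locus places alleles on a bounded integer lattice of repeat counts.
#' Genotyping software usually reports fragment lengths or arbitrary allele
#' codes; the `code_offset` declares the affine map from stored allele codes
#' to repeat counts (`repeat = code - code_offset`), identity by default.
#'
#' @param name Locus name.
#' @param motif_length Length in bases of the repeated motif (e.g. 2 or 4).
#' @param repeat_min,repeat_max Integer bounds of the allele lattice, in
#'   repeat units. The default upper bound of 35 comfortably exceeds typical
#'   primate microsatellite allele lengths (at most 33 repeats in the red
#'   colobus data this package's defaults emulate).
#' @param code_offset Integer subtracted from file allele codes to obtain
#'   repeat counts.
#' @param global_cap Largest admissible `repeat_max`.
#' @return An object of class `"msat_locus"`.
#' @export
locus <- function(name, motif_length = 2L, repeat_min = 1L, repeat_max = 35L,
                  code_offset = 0L, global_cap = 35L) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  motif_length <- as.integer(motif_length)
  repeat_min <- as.integer(repeat_min)
  repeat_max <- as.integer(repeat_max)
  if (motif_length < 1L) stop("motif_length must be >= 1")
  if (repeat_min >= repeat_max) stop("repeat_min must be < repeat_max")
  if (repeat_max > global_cap) {
    stop(sprintf("repeat_max (%d) exceeds the global cap (%d) for locus %s",
                 repeat_max, global_cap, name))
  }
  structure(list(name = name, motif_length = motif_length,
                 repeat_min = repeat_min, repeat_max = repeat_max,
                 code_offset = as.integer(code_offset)),
            class = "msat_locus")
}

#' Assemble a diploid genotype matrix
#'
#' Calls are unordered pairs of repeat counts; internally the smaller allele
#' is stored first. Missing genotypes are `NA` in both allele slots.
#'
#' @param allele1,allele2 Integer matrices (individuals x loci) of repeat
#'   counts; `NA` marks a missing call (both slots must agree on missingness).
#' @param groups Character vector of group labels, one per individual.
#' @param loci List of [locus()] objects, one per column.
#' @param ids Individual identifiers; defaults to `ind1..indN`.
#' @return An object of class `"genotype_matrix"` with elements `a1`, `a2`,
#'   `groups`, `loci`, `ids`.
#' @export
genotype_matrix <- function(allele1, allele2, groups, loci, ids = NULL) {
  allele1 <- as.matrix(allele1)
  allele2 <- as.matrix(allele2)
  storage.mode(allele1) <- "integer"
  storage.mode(allele2) <- "integer"
  n <- nrow(allele1)
  L <- ncol(allele1)
  stopifnot(identical(dim(allele1), dim(allele2)),
            length(groups) == n, length(loci) == L)
  if (is.null(ids)) ids <- paste0("ind", seq_len(n))
  stopifnot(length(ids) == n, !anyDuplicated(ids))
  if (!all(is.na(allele1) == is.na(allele2))) {
    stop("half-missing calls are not allowed: NA must appear in both alleles")
  }
  # unordered pairs: store sorted
  swap <- !is.na(allele1) & allele1 > allele2
  if (any(swap)) {
    tmp <- allele1[swap]
    allele1[swap] <- allele2[swap]
    allele2[swap] <- tmp
  }
  locus_names <- vapply(loci, function(l) l$name, character(1))
  if (anyDuplicated(locus_names)) stop("duplicated locus names")
  for (j in seq_len(L)) {
    lo <- loci[[j]]
    vals <- c(allele1[, j], allele2[, j])
    bad <- !is.na(vals) & (vals < lo$repeat_min | vals > lo$repeat_max)
    if (any(bad)) {
      stop(sprintf("locus %s: allele(s) %s outside lattice [%d, %d]",
                   lo$name, paste(unique(vals[bad]), collapse = ","),
                   lo$repeat_min, lo$repeat_max))
    }
  }
  dimnames(allele1) <- dimnames(allele2) <- list(ids, locus_names)
  names(loci) <- locus_names
  structure(list(a1 = allele1, a2 = allele2,
                 groups = as.character(groups), loci = loci, ids = ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d loci, %d group(s)\n",
              nrow(x$a1), ncol(x$a1), length(unique(x$groups))))
  miss <- mean(is.na(x$a1))
  cat(sprintf("missing calls: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Number of individuals / loci in a genotype matrix
#' @param g A [genotype_matrix()].
#' @return Integer count.
#' @export
n_individuals <- function(g) nrow(g$a1)

#' @rdname n_individuals
#' @export
n_loci <- function(g) ncol(g$a1)

#' Locus names of a genotype matrix
#' @param g A [genotype_matrix()].
#' @return Character vector.
#' @export
locus_names <- function(g) colnames(g$a1)

resolve_locus <- function(g, locus) {
  if (inherits(locus, "msat_locus")) locus <- locus$name
  if (is.character(locus)) {
    j <- match(locus, locus_names(g))
    if (is.na(j)) stop(sprintf("locus '%s' not present", locus))
    return(j)
  }
  j <- as.integer(locus)
  if (j < 1L || j > n_loci(g)) stop("locus index out of range")
  j
}

#' Drop loci from a genotype matrix
#' @param g A [genotype_matrix()].
#' @param drop Character vector of locus names to remove.
#' @return A reduced [genotype_matrix()].
#' @export
exclude_loci <- function(g, drop) {
  keep <- setdiff(locus_names(g), drop)
  if (length(keep) == 0L) stop("cannot drop every locus")
  genotype_matrix(g$a1[, keep, drop = FALSE], g$a2[, keep, drop = FALSE],
                  g$groups, g$loci[keep], ids = g$ids)
}

#' Subset individuals of a genotype matrix
#' @param g A [genotype_matrix()].
#' @param idx Integer or logical index over individuals.
#' @return A reduced [genotype_matrix()].
#' @export
subset_individuals <- function(g, idx) {
  genotype_matrix(g$a1[idx, , drop = FALSE], g$a2[idx, , drop = FALSE],
                  g$groups[idx], g$loci, ids = g$ids[idx])
}

# All non-missing gene copies at locus j (2 per genotyped individual).
gene_copies <- function(g, j) {
  v <- c(g$a1[, j], g$a2[, j])
  v[!is.na(v)]
}

# Number of genotyped individuals at locus j.
n_genotyped <- function(g, j) sum(!is.na(g$a1[, j]))

#' Allele frequencies at one locus
#'
#' Frequencies are computed over the `2N` non-missing gene copies.
#'
#' @param g A [genotype_matrix()].
#' @param locus Locus name, index or [locus()] object.
#' @return Named numeric vector of frequencies (names are repeat counts),
#'   summing to 1.
#' @export
allele_frequencies <- function(g, locus) {
  j <- resolve_locus(g, locus)
  copies <- gene_copies(g, j)
  if (length(copies) == 0L) {
    stop(sprintf("locus %s has no genotyped individuals", locus_names(g)[j]))
  }
  tab <- table(copies)
  freqs <- as.numeric(tab) / length(copies)
  names(freqs) <- names(tab)
  freqs
}

# ---- GenePop I/O ------------------------------------------------------------

format_code <- function(repeats, offset, digits) {
  code <- ifelse(is.na(repeats), 0L, repeats + offset)
  formatC(code, width = digits, flag = "0")
}

#' Write a genotype matrix in GenePop format
#'
#' @param g A [genotype_matrix()].
#' @param path Output file.
#' @param title Title line.
#' @param digits Allele-code width (2 or 3); `0` encodes missing.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(g, path, title = "msatdemog export", digits = 3L) {
  stopifnot(digits %in% c(2L, 3L))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(locus_names(g), con)
  for (grp in unique(g$groups)) {
    writeLines("POP", con)
    for (i in which(g$groups == grp)) {
      codes <- vapply(seq_len(n_loci(g)), function(j) {
        off <- g$loci[[j]]$code_offset
        paste0(format_code(g$a1[i, j], off, digits),
               format_code(g$a2[i, j], off, digits))
      }, character(1))
      writeLines(paste0(g$ids[i], " ,  ", paste(codes, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read a GenePop file
#'
#' Supports the common GenePop 4.x dialect: a title line, one locus name per
#' line (or a single comma-separated line), and `POP` blocks of
#' `id , 010012 ...` records with 2- or 3-digit allele codes where `0` is
#' missing. Allele codes are mapped to repeat counts through each locus's
#' `code_offset` (identity by default). POP blocks become group labels
#' `pop1..popK` unless the last individual id of a block is used as label.
#'
#' @param path GenePop file.
#' @param loci Optional list of [locus()] objects (by name) declaring lattice
#'   bounds and code offsets; loci absent from the list get defaults wide
#'   enough for the observed alleles.
#' @param global_cap Upper bound passed to default-constructed loci.
#' @return A [genotype_matrix()].
#' @export
read_genepop <- function(path, loci = NULL, global_cap = 35L) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("malformed GenePop file: fewer than 3 lines")
  lines <- sub("\r$", "", lines)
  pop_idx <- grep("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  if (length(pop_idx) == 0L) stop("malformed GenePop file: no POP line")
  header <- lines[2:(pop_idx[1] - 1L)]
  lnames <- unlist(strsplit(paste(header, collapse = ","), ","))
  lnames <- trimws(lnames)
  lnames <- lnames[nzchar(lnames)]
  L <- length(lnames)
  if (L == 0L) stop("malformed GenePop file: no locus names before first POP")

  ids <- character(0); groups <- character(0)
  rows1 <- list(); rows2 <- list()
  block <- 0L
  i <- pop_idx[1]
  while (i <= length(lines)) {
    line <- lines[i]
    if (grepl("^\\s*pop\\s*$", line, ignore.case = TRUE)) {
      block <- block + 1L
      if (i == length(lines) ||
          grepl("^\\s*pop\\s*$", lines[i + 1L], ignore.case = TRUE)) {
        warning(sprintf("empty POP block %d in %s", block, path))
      }
      i <- i + 1L
      next
    }
    if (!nzchar(trimws(line))) { i <- i + 1L; next }
    parts <- strsplit(line, ",")[[1]]
    if (length(parts) < 2L) {
      stop(sprintf("GenePop parse error at line %d: no comma separator", i))
    }
    id <- trimws(parts[1])
    codes <- strsplit(trimws(paste(parts[-1], collapse = ",")), "\\s+")[[1]]
    if (length(codes) != L) {
      stop(sprintf("GenePop parse error at line %d: %d genotype fields, expected %d",
                   i, length(codes), L))
    }
    digs <- unique(nchar(codes))
    if (length(digs) != 1L || !(digs %in% c(4L, 6L))) {
      stop(sprintf("GenePop parse error at line %d: allele codes must be 4 or 6 digits",
                   i))
    }
    d <- digs / 2L
    c1 <- as.integer(substr(codes, 1L, d))
    c2 <- as.integer(substr(codes, d + 1L, 2L * d))
    if (anyNA(c1) || anyNA(c2)) {
      stop(sprintf("GenePop parse error at line %d: non-numeric allele code", i))
    }
    c1[c1 == 0L] <- NA_integer_; c2[c2 == 0L] <- NA_integer_
    # a genotype with one null-scored allele is treated as missing entirely
    half <- xor(is.na(c1), is.na(c2))
    c1[half] <- NA_integer_; c2[half] <- NA_integer_
    ids <- c(ids, id)
    groups <- c(groups, paste0("pop", block))
    rows1[[length(rows1) + 1L]] <- c1
    rows2[[length(rows2) + 1L]] <- c2
    i <- i + 1L
  }
  a1 <- do.call(rbind, rows1); a2 <- do.call(rbind, rows2)
  if (is.null(a1)) a1 <- a2 <- matrix(NA_integer_, 0L, L)
  if (anyDuplicated(ids)) ids <- make.unique(ids)

  full_loci <- vector("list", L)
  for (j in seq_len(L)) {
    given <- if (!is.null(loci)) {
      hit <- vapply(loci, function(l) identical(l$name, lnames[j]), logical(1))
      if (any(hit)) loci[[which(hit)[1]]] else NULL
    }
    if (!is.null(given)) {
      full_loci[[j]] <- given
      off <- given$code_offset
      a1[, j] <- a1[, j] - off
      a2[, j] <- a2[, j] - off
    } else {
      obs <- c(a1[, j], a2[, j])
      obs <- obs[!is.na(obs)]
      hi <- if (length(obs)) max(obs, global_cap %/% 2L) else global_cap
      full_loci[[j]] <- locus(lnames[j], repeat_min = 1L,
                              repeat_max = min(max(hi, 2L), global_cap),
                              global_cap = global_cap)
    }
  }
  genotype_matrix(a1, a2, groups, full_loci, ids = ids)
}

# ---- CSV I/O ----------------------------------------------------------------

#' Write a genotype matrix as CSV
#'
#' One row per individual with columns `id,group,<locus>_1,<locus>_2`;
#' missing alleles are empty cells.
#'
#' @param g A [genotype_matrix()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genotype_csv <- function(g, path) {
  df <- data.frame(id = g$ids, group = g$groups, stringsAsFactors = FALSE)
  for (j in seq_len(n_loci(g))) {
    nm <- locus_names(g)[j]
    df[[paste0(nm, "_1")]] <- g$a1[, j]
    df[[paste0(nm, "_2")]] <- g$a2[, j]
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read genotypes from CSV
#'
#' @param path CSV file in the layout written by [write_genotype_csv()].
#' @param loci Optional list of [locus()] objects by name.
#' @param global_cap Upper lattice bound for default-constructed loci.
#' @return A [genotype_matrix()].
#' @export
read_genotype_csv <- function(path, loci = NULL, global_cap = 35L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "group") %in% names(df))) {
    stop("CSV must contain 'id' and 'group' columns")
  }
  acols <- grep("_[12]$", names(df), value = TRUE)
  lnames <- unique(sub("_[12]$", "", acols))
  a1 <- sapply(lnames, function(nm) as.integer(df[[paste0(nm, "_1")]]))
  a2 <- sapply(lnames, function(nm) as.integer(df[[paste0(nm, "_2")]]))
  a1 <- matrix(a1, nrow = nrow(df), dimnames = list(NULL, lnames))
  a2 <- matrix(a2, nrow = nrow(df), dimnames = list(NULL, lnames))
  full_loci <- lapply(lnames, function(nm) {
    if (!is.null(loci)) {
      hit <- vapply(loci, function(l) identical(l$name, nm), logical(1))
      if (any(hit)) return(loci[[which(hit)[1]]])
    }
    obs <- c(a1[, nm], a2[, nm]); obs <- obs[!is.na(obs)]
    hi <- if (length(obs)) max(obs, global_cap %/% 2L) else global_cap
    locus(nm, repeat_min = 1L, repeat_max = min(max(hi, 2L), global_cap),
          global_cap = global_cap)
  })
  genotype_matrix(a1, a2, df$group, full_loci, ids = as.character(df$id))
}

# ---- locus-level QC ---------------------------------------------------------

#' Screen loci for null alleles and homozygote excess
#'
#' Estimates the null-allele frequency at each polymorphic locus with the
#' Brookfield (1996) estimator `(He - Ho) / (1 + He)` and tests for a
#' homozygote excess by a one-sided randomization test: gene copies are
#' re-paired into diploids at random (Hardy-Weinberg resampling) and the
#' observed heterozygote count is compared with its randomization
#' distribution. P-values are corrected across loci by the sequential
#' Bonferroni (Holm) procedure; significant loci are recommended for
#' exclusion.
#'
#' @param g A [genotype_matrix()].
#' @param n_perm Number of randomizations.
#' @param alpha Family-wise significance level.
#' @param seed Optional RNG seed.
#' @return A data frame of class `"qc_report"` with one row per locus:
#'   `locus`, `assessable`, `null_freq`, `p_homozygote_excess`,
#'   `flagged`, `exclude`.
#' @export
screen_null_alleles <- function(g, n_perm = 1000L, alpha = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- n_loci(g)
  out <- data.frame(locus = locus_names(g), assessable = FALSE,
                    null_freq = NA_real_, p_homozygote_excess = NA_real_,
                    flagged = FALSE, exclude = FALSE,
                    stringsAsFactors = FALSE)
  for (j in seq_len(L)) {
    copies <- gene_copies(g, j)
    if (length(unique(copies)) < 2L) next   # monomorphic: not assessable
    out$assessable[j] <- TRUE
    hh <- heterozygosities(g, j)
    out$null_freq[j] <- (hh[["He"]] - hh[["Ho"]]) / (1 + hh[["He"]])
    n <- length(copies) %/% 2L
    ho_obs <- sum(g$a1[, j] != g$a2[, j], na.rm = TRUE)
    ho_sim <- integer(n_perm)
    for (b in seq_len(n_perm)) {
      perm <- sample(copies)
      ho_sim[b] <- sum(perm[seq_len(n)] != perm[n + seq_len(n)])
    }
    # one-sided: excess of homozygotes = deficit of heterozygotes
    out$p_homozygote_excess[j] <- (1 + sum(ho_sim <= ho_obs)) / (n_perm + 1)
  }
  ok <- which(out$assessable)
  if (length(ok)) {
    rej <- sequential_bonferroni(out$p_homozygote_excess[ok], alpha)
    out$flagged[ok] <- rej & out$null_freq[ok] > 0
    out$exclude <- out$flagged
  }
  class(out) <- c("qc_report", class(out))
  out
}

#' Write a QC report as TSV and JSON
#'
#' @param report A `"qc_report"` from [screen_null_alleles()].
#' @param tsv,json Output paths (either may be `NULL` to skip).
#' @return Invisibly, the report.
#' @export
write_qc_report <- function(report, tsv = NULL, json = NULL) {
  if (!is.null(tsv)) {
    utils::write.table(report, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(report, json, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  invisible(report)
}
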