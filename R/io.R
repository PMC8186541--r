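#' Read a pedigree file
#'
#' Three-column delimited text (animal, sire, dam), `0` = unknown parent.
#' A header line is auto-detected (first field equal to `animal`, case
#' insensitive).
#'
#' @param path file path.
#' @param sep field separator; default whitespace.
#' @return a [pedigree()] object.
#' @export
read_pedigree <- function(path, sep = "") {
  first <- readLines(path, n = 1)
  header <- grepl("^\\s*animal\\b", tolower(first))
  d <- utils::read.table(path, header = header, sep = sep,
                         colClasses = "character")
  if (ncol(d) < 3) stop("pedigree file needs 3 columns (animal, sire, dam)")
  pedigree(d[[1]], d[[2]], d[[3]])
}

#' @rdname read_pedigree
#' @param ped pedigree to write.
#' @export
write_pedigree <- function(ped, path) {
  par <- function(v) ifelse(v == 0, "0", ped$id[v])
  utils::write.table(
    data.frame(animal = ped$id, sire = par(ped$sire), dam = par(ped$dam)),
    path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}

#' Read a phenotype / fixed-effect table
#'
#' Delimited text with a header line; the first column (or the column
#' named in `id_col`) holds animal identifiers.
#'
#' @param path file path.
#' @param sep separator (default whitespace).
#' @param id_col id column name; default first column.
#' @return data.frame with the id column coerced to character.
#' @export
read_phenotypes <- function(path, sep = "", id_col = NULL) {
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  if (is.null(id_col)) id_col <- names(d)[1]
  d[[id_col]] <- as.character(d[[id_col]])
  d
}

#' Read PLINK-style genotypes
#'
#' Accepts either a `.ped`/`.map` pair (pass the common prefix or the
#' `.ped` path) or a PLINK-recoded additive `.raw` file. In `.ped`
#' dialect the first six columns are family, id, sire, dam, sex,
#' phenotype, followed by two allele calls per SNP with `0` for missing;
#' the counted allele of each SNP is the alphabetically smallest observed
#' allele (stored in the result's `counted_allele` attribute). `.raw`
#' files carry dosages (0/1/2, `NA` missing) directly.
#'
#' @param path prefix, `.ped` path, or `.raw` path.
#' @return a [genotypes()] object (observed allele frequencies).
#' @export
read_plink <- function(path) {
  if (grepl("\\.raw$", path)) return(read_plink_raw(path))
  prefix <- sub("\\.ped$", "", path)
  pedf <- paste0(prefix, ".ped"); mapf <- paste0(prefix, ".map")
  if (!file.exists(pedf)) stop("no such file: ", pedf)
  if (!file.exists(mapf)) stop("no such file: ", mapf)
  map <- utils::read.table(mapf, colClasses = c("integer", "character",
                                                "numeric", "integer"))
  names(map) <- c("chr", "snp", "cm", "pos")
  lines <- readLines(pedf)
  toks <- strsplit(trimws(lines), "\\s+")
  m <- nrow(map)
  want <- 6 + 2 * m
  bad <- which(lengths(toks) != want)
  if (length(bad))
    stop("ragged .ped row at line ", bad[1], ": expected ", want,
         " fields, found ", lengths(toks)[bad[1]])
  ids <- vapply(toks, `[`, "", 2)
  al <- t(vapply(toks, function(x) x[-(1:6)], character(2 * m)))
  a1 <- al[, seq(1, 2 * m, 2), drop = FALSE]
  a2 <- al[, seq(2, 2 * m, 2), drop = FALSE]
  dos <- matrix(NA_real_, length(ids), m)
  counted <- character(m)
  for (j in seq_len(m)) {
    obs <- c(a1[, j], a2[, j])
    alleles <- sort(setdiff(unique(obs), "0"))
    if (length(alleles) > 2)
      stop("more than two alleles for SNP ", map$snp[j], ": ",
           paste(alleles, collapse = "/"))
    counted[j] <- if (length(alleles)) alleles[1] else NA_character_
    miss <- a1[, j] == "0" | a2[, j] == "0"
    dos[, j] <- (a1[, j] == counted[j]) + (a2[, j] == counted[j])
    dos[miss, j] <- NA
  }
  g <- genotypes(dos, map = map[, c("snp", "chr", "pos")], ids = ids)
  attr(g, "counted_allele") <- stats::setNames(counted, map$snp)
  g
}

read_plink_raw <- function(path) {
  d <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                         na.strings = c("NA", "-9"))
  fixed <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(fixed %in% names(d)))
    stop(".raw file must carry the six standard leading columns")
  snps <- setdiff(names(d), fixed)
  dos <- as.matrix(d[, snps, drop = FALSE])
  if (any(!is.na(dos) & !(dos %in% 0:2)))
    stop("allele-dosage violation in .raw file (values outside 0/1/2)")
  colnames(dos) <- sub("_[ACGTB012]+$", "", snps)
  genotypes(dos, ids = as.character(d$IID))
}

#' Write genotypes in PLINK dialects
#'
#' `write_plink()` writes a `.ped`/`.map` pair (counted allele written as
#' `A`, the other as `B`, missing as `0 0`); `write_plink_raw()` writes
#' the additive `.raw` dialect.
#'
#' @param geno a [genotypes()] object.
#' @param prefix output prefix (`.ped`/`.map` appended).
#' @param ped optional [pedigree()] supplying sire/dam columns.
#' @return invisible output path(s).
#' @export
write_plink <- function(geno, prefix, ped = NULL) {
  map <- geno$map
  utils::write.table(
    data.frame(map$chr, map$snp, 0, map$pos),
    paste0(prefix, ".map"), row.names = FALSE, col.names = FALSE,
    quote = FALSE, sep = "\t")
  n <- length(geno$ids)
  sire <- dam <- rep("0", n)
  if (!is.null(ped)) {
    pos <- match(geno$ids, ped$id)
    par <- function(v) ifelse(is.na(pos) | v[pos] == 0, "0", ped$id[v[pos]])
    sire <- par(ped$sire); dam <- par(ped$dam)
  }
  code <- c("B B", "A B", "A A")
  gcol <- apply(geno$dosages, 1, function(x)
    paste(ifelse(is.na(x), "0 0", code[x + 1]), collapse = " "))
  lines <- paste("FAM1", geno$ids, sire, dam, "0", "-9", gcol)
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(paste0(prefix, c(".ped", ".map")))
}

#' @rdname write_plink
#' @param path output path for the `.raw` file.
#' @export
write_plink_raw <- function(geno, path) {
  d <- data.frame(FID = "FAM1", IID = geno$ids, PAT = 0, MAT = 0, SEX = 0,
                  PHENOTYPE = -9)
  dos <- as.data.frame(geno$dosages)
  names(dos) <- paste0(geno$map$snp, "_A")
  utils::write.table(cbind(d, dos), path, row.names = FALSE, quote = FALSE,
                     sep = " ")
  invisible(path)
}

#' Export / import a symmetric matrix as sparse triplet text
#'
#' Three columns (i, j, value), lower triangle only, ids resolved through
#' a header comment line. Intended for debugging and diffable outputs.
#'
#' @param M symmetric matrix (dense or sparse) with dimnames.
#' @param path output path.
#' @return invisible path; the reader returns a dense symmetric matrix.
#' @export
write_sparse_matrix <- function(M, path) {
  ids <- rownames(M)
  Md <- as.matrix(M)
  idx <- which(lower.tri(Md, diag = TRUE) & Md != 0, arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ids: ", paste(ids, collapse = ",")), con)
  utils::write.table(data.frame(i = idx[, 1], j = idx[, 2],
                                value = Md[idx]),
                     con, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_sparse_matrix
#' @export
read_sparse_matrix <- function(path) {
  first <- readLines(path, n = 1)
  ids <- strsplit(sub("^# ids: ", "", first), ",")[[1]]
  d <- utils::read.table(path, header = TRUE, skip = 1)
  n <- length(ids)
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  M[cbind(d$i, d$j)] <- d$value
  M[cbind(d$j, d$i)] <- d$value
  M
}

#' Write a GWAS result table
#'
#' Tab-delimited, one row per SNP, columns snp, chr, pos, freq, effect,
#' se, t, p, p_adj, flag, sorted by (chr, pos).
#'
#' @param result a `gwas_result` data.frame.
#' @param path output path.
#' @export
write_gwas_results <- function(result, path) {
  cols <- c("snp", "chr", "pos", "freq", "effect", "se", "t", "p",
            "p_adj", "flag")
  utils::write.table(as.data.frame(result)[, cols], path,
                     row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}

#' Write mixed-model solutions
#'
#' Delimited text (id, solution, se) for the breeding values of a solved
#' system; standard errors are prediction-error standard deviations.
#'
#' @param system a solved `mme` object.
#' @param path output path.
#' @param component genetic component; default 1.
#' @export
write_solutions <- function(system, path, component = 1L) {
  u <- system$u[[component]]
  pev <- diag(extract_pev_block(system, component = component))
  utils::write.table(
    data.frame(id = names(u), solution = as.numeric(u),
               se = sqrt(pmax(pev, 0))),
    path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}
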