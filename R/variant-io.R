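#' @include PoolSnpSet-methods.R
NULL

.gtToDosage <- function(gt) {
  gt <- sub(":.*$", "", gt)
  out <- rep(NA_integer_, length(gt))
  known <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L,
             "0|1" = 1L, "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)
  hit <- match(gt, names(known))
  out[!is.na(hit)] <- known[hit[!is.na(hit)]]
  out
}

#' Read a VCF into a PoolSnpSet
#'
#' Reads a VCF 4.x file with per-sample allelic depths (`AD`) for the
#' sequencing pools and genotypes (`GT`) for the wild individuals, and
#' returns the biallelic SNP records as a [PoolSnpSet-class]. Indel
#' records (allele length differs) are skipped; read them with
#' [readVcfIndels()]. Site quality and the `QD`, `FS` and
#' `ReadPosRankSum` INFO annotations are carried along for filtering.
#'
#' @param path path to a VCF file (plain or gzipped).
#' @param poolSizes named integer vector: diploid individuals per pool;
#'   the names select the pool sample columns of the VCF.
#' @param wildSamples character vector of wild-individual sample names
#'   (genotypes are read from their `GT` fields).
#' @param multiallelic `"drop"` removes multi-allelic sites; `"split"`
#'   emits one biallelic record per alternate allele.
#' @return A [PoolSnpSet-class] sorted by (chrom, pos).
#' @seealso [readSync()], [writePoolVcf()]
#' @export
readVcfPools <- function(path, poolSizes, wildSamples = character(),
                         multiallelic = c("drop", "split")) {
  multiallelic <- match.arg(multiallelic)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0L) {
    return(PoolSnpSet(
      GRanges(character(), IRanges(integer(), width = 1L),
              ref = character(), alt = character()),
      refCounts = matrix(integer(), 0L, length(poolSizes),
                         dimnames = list(NULL, names(poolSizes))),
      altCounts = matrix(integer(), 0L, length(poolSizes),
                         dimnames = list(NULL, names(poolSizes))),
      poolSizes = poolSizes,
      wildGeno = matrix(integer(), 0L, length(wildSamples),
                        dimnames = list(NULL, wildSamples))))
  }
  samples <- colnames(v@gt)[-1L]
  missing <- setdiff(c(names(poolSizes), wildSamples), samples)
  if (length(missing))
    stop("sample(s) not present in VCF: ", paste(missing, collapse = ", "))

  ref <- fix[, "REF"]
  altField <- fix[, "ALT"]
  altList <- strsplit(altField, ",", fixed = TRUE)
  nAlt <- lengths(altList)

  ad <- vcfR::extract.gt(v, element = "AD")
  gt <- vcfR::extract.gt(v, element = "GT")

  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  qd <- vcfR::extract.info(v, element = "QD", as.numeric = TRUE)
  fs <- vcfR::extract.info(v, element = "FS", as.numeric = TRUE)
  rprs <- vcfR::extract.info(v, element = "ReadPosRankSum", as.numeric = TRUE)

  expandRow <- function(i) {
    alts <- altList[[i]]
    if (length(alts) > 1L && multiallelic == "drop") return(NULL)
    lapply(seq_along(alts), function(k) list(row = i, altIdx = k,
                                             alt = alts[k]))
  }
  recs <- unlist(lapply(seq_len(nrow(fix)), expandRow), recursive = FALSE)
  if (!length(recs)) recs <- list()
  keepSnp <- vapply(recs, function(r)
    nchar(ref[r$row]) == 1L && nchar(r$alt) == 1L && r$alt != ref[r$row],
    logical(1))
  recs <- recs[keepSnp]
  rows <- vapply(recs, `[[`, 0L, "row")
  altIdx <- vapply(recs, `[[`, 0L, "altIdx")
  alts <- vapply(recs, `[[`, "", "alt")

  pickAD <- function(sample) {
    parts <- strsplit(ifelse(is.na(ad[, sample]), ".", ad[, sample]),
                      ",", fixed = TRUE)
    refc <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
    altc <- suppressWarnings(as.integer(mapply(function(p, k)
      if (length(p) >= k + 1L) p[k + 1L] else NA_character_,
      parts[rows], altIdx)))
    refc <- refc[rows]
    refc[is.na(refc)] <- 0L
    altc[is.na(altc)] <- 0L
    cbind(refc, altc)
  }
  nrec <- length(rows)
  refM <- matrix(0L, nrec, length(poolSizes),
                 dimnames = list(NULL, names(poolSizes)))
  altM <- refM
  for (p in names(poolSizes)) {
    m <- pickAD(p)
    refM[, p] <- m[, 1L]
    altM[, p] <- m[, 2L]
  }
  wild <- matrix(NA_integer_, nrec, length(wildSamples),
                 dimnames = list(NULL, wildSamples))
  for (w in wildSamples)
    wild[, w] <- .gtToDosage(gt[rows, w])
  ## genotype dosages other than 0/0|0/1|1/1 only make sense for the
  ## biallelic alt 1; treat them as missing for split alts
  if (any(altIdx > 1L) && length(wildSamples))
    wild[altIdx > 1L, ] <- NA_integer_

  g <- GRanges(fix[rows, "CHROM"],
               IRanges(as.integer(fix[rows, "POS"]), width = 1L),
               ref = unname(ref[rows]), alt = alts)
  PoolSnpSet(g, refM, altM, poolSizes, wildGeno = wild,
             qual = qual[rows],
             info = data.frame(QD = qd[rows], FS = fs[rows],
                               ReadPosRankSum = rprs[rows]))
}

#' Read indel records from a VCF
#'
#' Returns records whose reference and alternate alleles differ in
#' length as a data.frame ready for [applyIndelFilters()].
#'
#' @param path path to a VCF file.
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `qual`, `QD`, `FS`, `ReadPosRankSum`, sorted by (chrom, pos).
#' @export
readVcfIndels <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  empty <- data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      qual = numeric(), QD = numeric(), FS = numeric(),
                      ReadPosRankSum = numeric())
  if (is.null(fix) || nrow(fix) == 0L) return(empty)
  keep <- !grepl(",", fix[, "ALT"], fixed = TRUE) &
    nchar(fix[, "REF"]) != nchar(fix[, "ALT"])
  if (!any(keep)) return(empty)
  out <- data.frame(
    chrom = fix[keep, "CHROM"],
    pos = as.integer(fix[keep, "POS"]),
    ref = fix[keep, "REF"],
    alt = fix[keep, "ALT"],
    qual = suppressWarnings(as.numeric(fix[keep, "QUAL"])),
    QD = vcfR::extract.info(v, element = "QD", as.numeric = TRUE)[keep],
    FS = vcfR::extract.info(v, element = "FS", as.numeric = TRUE)[keep],
    ReadPosRankSum = vcfR::extract.info(
      v, element = "ReadPosRankSum", as.numeric = TRUE)[keep])
  out[order(out$chrom, out$pos), , drop = FALSE]
}

.SYNC_BASES <- c("A", "T", "C", "G", "N", "del")

#' Read a sync-style pooled allele-count table
#'
#' Parses the whitespace-delimited pool-seq "sync" dialect: one row per
#' site with `chrom pos refBase` followed by one `A:T:C:G:N:del` count
#' column per pool. The alternate allele is inferred as the non-reference
#' base with the largest summed count across pools (ties broken in
#' A,T,C,G order; monomorphic sites get the first other base with zero
#' counts and fall to the MAF filter downstream).
#'
#' @param path path to the sync file.
#' @param poolSizes named integer vector of diploid individuals per
#'   pool, in column order.
#' @return A [PoolSnpSet-class] (no wild genotypes, no quality
#'   annotations).
#' @export
readSync <- function(path, poolSizes) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  nPool <- length(poolSizes)
  if (!length(lines)) {
    return(PoolSnpSet(
      GRanges(character(), IRanges(integer(), width = 1L),
              ref = character(), alt = character()),
      refCounts = matrix(integer(), 0L, nPool,
                         dimnames = list(NULL, names(poolSizes))),
      altCounts = matrix(integer(), 0L, nPool,
                         dimnames = list(NULL, names(poolSizes))),
      poolSizes = poolSizes))
  }
  fields <- strsplit(lines, "[ \t]+")
  bad <- which(lengths(fields) != 3L + nPool)
  if (length(bad))
    stop("malformed sync line ", bad[1L], ": expected ",
         3L + nPool, " fields, found ", length(fields[[bad[1L]]]))
  chrom <- vapply(fields, `[`, "", 1L)
  pos <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  if (anyNA(pos))
    stop("malformed sync line ", which(is.na(pos))[1L],
         ": position is not an integer")
  refBase <- toupper(vapply(fields, `[`, "", 3L))

  n <- length(lines)
  counts <- array(0L, dim = c(n, nPool, 6L))
  for (p in seq_len(nPool)) {
    col <- vapply(fields, `[`, "", 3L + p)
    sp <- strsplit(col, ":", fixed = TRUE)
    badc <- which(lengths(sp) != 6L)
    if (length(badc))
      stop("malformed sync line ", badc[1L],
           ": count column must have 6 ':'-separated fields")
    m <- suppressWarnings(matrix(as.integer(unlist(sp)), ncol = 6L,
                                 byrow = TRUE))
    if (anyNA(m))
      stop("malformed sync line ", which(rowSums(is.na(m)) > 0)[1L],
           ": non-integer base count")
    counts[, p, ] <- m
  }
  baseTotals <- apply(counts[, , 1:4, drop = FALSE], c(1L, 3L), sum)
  colnames(baseTotals) <- .SYNC_BASES[1:4]
  refIdx <- match(refBase, .SYNC_BASES[1:4])
  if (anyNA(refIdx))
    stop("malformed sync line ", which(is.na(refIdx))[1L],
         ": reference base must be one of A/T/C/G")
  altIdx <- integer(n)
  for (i in seq_len(n)) {
    others <- setdiff(1:4, refIdx[i])
    altIdx[i] <- others[which.max(baseTotals[i, others])]
  }
  idx <- cbind(rep(seq_len(n), nPool), rep(seq_len(nPool), each = n))
  refM <- matrix(counts[cbind(idx, refIdx[idx[, 1L]])], n, nPool,
                 dimnames = list(NULL, names(poolSizes)))
  altM <- matrix(counts[cbind(idx, altIdx[idx[, 1L]])], n, nPool,
                 dimnames = list(NULL, names(poolSizes)))
  g <- GRanges(chrom, IRanges(pos, width = 1L),
               ref = .SYNC_BASES[refIdx], alt = .SYNC_BASES[altIdx])
  PoolSnpSet(g, refM, altM, poolSizes)
}

#' Write a PoolSnpSet as a sync-style count table
#'
#' @param x A [PoolSnpSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSync <- function(x, path) {
  s <- sites(x)
  n <- length(x)
  pools <- poolNames(x)
  baseIdx <- function(b) match(b, .SYNC_BASES)
  ri <- baseIdx(s$ref); ai <- baseIdx(s$alt)
  cols <- lapply(seq_along(pools), function(p) {
    m <- matrix(0L, n, 6L)
    m[cbind(seq_len(n), ri)] <- refCounts(x)[, p]
    m[cbind(seq_len(n), ai)] <- altCounts(x)[, p]
    do.call(paste, c(lapply(seq_len(6L), function(j) m[, j]),
                     list(sep = ":")))
  })
  lines <- do.call(paste, c(
    list(as.character(seqnames(s)), start(s), s$ref),
    cols, list(sep = "\t")))
  if (!n) lines <- character()
  writeLines(lines, path)
  invisible(path)
}

#' Write a PoolSnpSet as a minimal VCF
#'
#' Emits a VCF 4.2 file with one sample column per pool (pooled allelic
#' depths in `AD`, genotype `./.`) and one per wild individual (diploid
#' `GT`), plus `QD`/`FS`/`ReadPosRankSum` INFO annotations when present.
#' The file round-trips through [readVcfPools()].
#'
#' @param x A [PoolSnpSet-class].
#' @param path output path.
#' @param wildNames optional names for the wild sample columns.
#' @return `path`, invisibly.
#' @export
writePoolVcf <- function(x, path, wildNames = NULL) {
  s <- sites(x)
  n <- length(x)
  nw <- ncol(wildGenotypes(x))
  if (is.null(wildNames)) {
    wildNames <- colnames(wildGenotypes(x))
    if (is.null(wildNames) && nw)
      wildNames <- sprintf("wild%02d", seq_len(nw))
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=poolSweeps",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand bias\">",
    "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read position rank sum\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", poolNames(x), wildNames), collapse = "\t"))
  if (!n) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  info <- siteInfo(x)
  fmtNum <- function(v) ifelse(is.na(v), NA, format(v, trim = TRUE,
                                                    scientific = FALSE))
  addField <- function(cur, tag, v) {
    piece <- ifelse(is.na(v), NA, paste0(tag, "=", fmtNum(v)))
    ifelse(is.na(piece), cur,
           ifelse(nzchar(cur), paste0(cur, ";", piece), piece))
  }
  infoStr <- rep("", n)
  infoStr <- addField(infoStr, "QD", info$QD)
  infoStr <- addField(infoStr, "FS", info$FS)
  infoStr <- addField(infoStr, "ReadPosRankSum", info$ReadPosRankSum)
  infoStr[!nzchar(infoStr)] <- "."
  poolCols <- lapply(seq_along(poolNames(x)), function(p)
    paste0("./.:", refCounts(x)[, p], ",", altCounts(x)[, p]))
  gtStr <- c("0/0", "0/1", "1/1")
  wildCols <- lapply(seq_len(nw), function(w) {
    g <- wildGenotypes(x)[, w]
    out <- rep("./.:.", n)
    ok <- !is.na(g)
    out[ok] <- paste0(gtStr[g[ok] + 1L], ":.")
    out
  })
  body <- do.call(paste, c(
    list(as.character(seqnames(s)), start(s), ".", s$ref, s$alt,
         ifelse(is.na(siteQual(x)), ".", fmtNum(siteQual(x))),
         ".", infoStr, "GT:AD"),
    poolCols, wildCols, list(sep = "\t")))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read/write the package's snp-table TSV
#'
#' A self-contained tab-separated representation of a [PoolSnpSet-class]
#' used between pipeline stages: site columns (`chrom`, `pos`, `ref`,
#' `alt`, `qual`, `QD`, `FS`, `ReadPosRankSum`), per-pool read counts
#' (`ref_<pool>`, `alt_<pool>`) and per-individual wild dosages
#' (`gt_<id>`), with pool sizes recorded on a `#poolSizes:` header line.
#'
#' @param x A [PoolSnpSet-class].
#' @param path file path.
#' @return `writeSnpTable()` returns `path` invisibly; `readSnpTable()`
#'   returns a [PoolSnpSet-class].
#' @export
writeSnpTable <- function(x, path) {
  s <- sites(x)
  df <- data.frame(chrom = as.character(seqnames(s)), pos = start(s),
                   ref = s$ref, alt = s$alt, qual = siteQual(x),
                   QD = siteInfo(x)$QD, FS = siteInfo(x)$FS,
                   ReadPosRankSum = siteInfo(x)$ReadPosRankSum,
                   check.names = FALSE)
  for (p in poolNames(x)) {
    df[[paste0("ref_", p)]] <- refCounts(x)[, p]
    df[[paste0("alt_", p)]] <- altCounts(x)[, p]
  }
  g <- wildGenotypes(x)
  for (w in seq_len(ncol(g)))
    df[[paste0("gt_", colnames(g)[w])]] <- g[, w]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#poolSizes: ",
                    paste(poolNames(x), x@poolSizes, sep = "=",
                          collapse = ",")), con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' @rdname writeSnpTable
#' @export
readSnpTable <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#poolSizes:"))
    stop("not a poolSweeps snp table: missing #poolSizes header")
  spec <- strsplit(trimws(sub("^#poolSizes:", "", first)), ",",
                   fixed = TRUE)[[1L]]
  kv <- strsplit(spec, "=", fixed = TRUE)
  poolSizes <- setNames(as.integer(vapply(kv, `[`, "", 2L)),
                        vapply(kv, `[`, "", 1L))
  df <- read.table(path, header = TRUE, sep = "\t", skip = 1L,
                   check.names = FALSE, colClasses = NA,
                   stringsAsFactors = FALSE)
  pools <- names(poolSizes)
  gtCols <- grep("^gt_", colnames(df), value = TRUE)
  wild <- if (length(gtCols)) {
    m <- as.matrix(df[, gtCols, drop = FALSE])
    colnames(m) <- sub("^gt_", "", gtCols)
    m
  } else NULL
  if (nrow(df) == 0L) {
    return(PoolSnpSet(
      GRanges(character(), IRanges(integer(), width = 1L),
              ref = character(), alt = character()),
      refCounts = matrix(integer(), 0L, length(pools),
                         dimnames = list(NULL, pools)),
      altCounts = matrix(integer(), 0L, length(pools),
                         dimnames = list(NULL, pools)),
      poolSizes = poolSizes,
      wildGeno = if (is.null(wild)) NULL else wild[0L, , drop = FALSE]))
  }
  refM <- as.matrix(df[, paste0("ref_", pools), drop = FALSE])
  altM <- as.matrix(df[, paste0("alt_", pools), drop = FALSE])
  colnames(refM) <- colnames(altM) <- pools
  PoolSnpSet(
    GRanges(df$chrom, IRanges(df$pos, width = 1L),
            ref = as.character(df$ref), alt = as.character(df$alt)),
    refCounts = refM,
    altCounts = altM,
    poolSizes = poolSizes,
    wildGeno = wild,
    qual = df$qual,
    info = df[, c("QD", "FS", "ReadPosRankSum")])
}
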