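#' Read a site-level callset from VCF or TSV
#'
#' Reads variant records and normalises them to bi-allelic SNV site keys.
#' Records whose ref or alt is not a single base are filtered out;
#' multi-allelic records are either dropped (default, so only records that
#' are bi-allelic as reported survive) or split into per-allele keys with
#' the SNV alleles kept.
#'
#' VCF input goes through the standard parser; a `SUPPORT=` INFO field, as
#' written by [write_union_sites()], is carried into a `support` column.
#' TSV input needs header columns `chrom`, `pos`, `ref`, `alt`.
#'
#' @param path A `.vcf` (possibly sites-only) or TSV file.
#' @param caller_id Label for the resulting callset (default: file stem).
#' @param multiallelic `"drop"` or `"split"`.
#' @param chrom_order Optional chromosome order (genome-table order); when
#'   given, records on chromosomes absent from it are rejected.
#' @return A [callset()].
#' @export
read_sites <- function(path, caller_id = NULL,
                       multiallelic = c("drop", "split"),
                       chrom_order = NULL) {
  multiallelic <- match.arg(multiallelic)
  if (!file.exists(path)) stop("variant file not found: ", path)
  if (is.null(caller_id)) caller_id <- sub("\\.[^.]*$", "", basename(path))

  if (is_vcf(path)) {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcf@fix
    if (is.null(fix) || nrow(fix) == 0) {
      return(callset(data.frame(chrom = character(), pos = integer(),
                                ref = character(), alt = character()),
                     caller_id, chrom_order))
    }
    pos <- suppressWarnings(as.numeric(fix[, "POS"]))
    if (anyNA(pos))
      stop("malformed record (non-numeric POS) at record ",
           which(is.na(pos))[1], " of ", path)
    info <- fix[, "INFO"]
    support <- suppressWarnings(
      as.integer(sub("^.*SUPPORT=([0-9]+).*$", "\\1", info)))
    support[!grepl("SUPPORT=", info)] <- NA_integer_
    rec <- data.frame(chrom = fix[, "CHROM"], pos = pos,
                      ref = toupper(fix[, "REF"]), alt = toupper(fix[, "ALT"]),
                      support = support, stringsAsFactors = FALSE)
  } else {
    rec <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    miss <- setdiff(c("chrom", "pos", "ref", "alt"), names(rec))
    if (length(miss) > 0)
      stop("TSV callset missing column(s): ", paste(miss, collapse = ", "))
    rec$ref <- toupper(rec$ref)
    rec$alt <- toupper(rec$alt)
    if (!"support" %in% names(rec)) rec$support <- NA_integer_
  }
  if (anyNA(rec$ref) || anyNA(rec$alt))
    stop("malformed record (missing alleles) in ", path)

  multi <- grepl(",", rec$alt, fixed = TRUE)
  if (multiallelic == "split" && any(multi)) {
    alts <- strsplit(rec$alt, ",", fixed = TRUE)
    n <- lengths(alts)
    rec <- data.frame(chrom = rep(rec$chrom, n), pos = rep(rec$pos, n),
                      ref = rep(rec$ref, n), alt = unlist(alts),
                      support = rep(rec$support, n), stringsAsFactors = FALSE)
  } else {
    rec <- rec[!multi, , drop = FALSE]
  }
  snv <- rec$ref %in% BASES & rec$alt %in% BASES & rec$ref != rec$alt
  rec <- rec[snv, , drop = FALSE]
  if (all(is.na(rec$support))) rec$support <- NULL

  if (!is.null(chrom_order)) chrom_rank(rec$chrom, chrom_order)  # reject unknowns
  callset(rec, caller_id, chrom_order)
}

is_vcf <- function(path) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) return(TRUE)
  first <- readLines(path, n = 1)
  length(first) == 1 && startsWith(first, "##fileformat=VCF")
}

#' Write a sites-only VCF of the consensus union
#'
#' Emits the union site list of a consensus tally (or any callset) as a
#' sorted sites-only VCF, with per-site caller support in the INFO column
#' (`SUPPORT=k`). This is the file handed to the downstream genotype
#' likelihood stage.
#'
#' @param x A `consensus_result` (see [tally()]) or a [callset()]. If a
#'   callset has no `support` column, `SUPPORT` is omitted.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_union_sites <- function(x, path) {
  if (inherits(x, "consensus_result")) x <- x$sites
  stopifnot(is.data.frame(x))
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Number of callers reporting the site\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (nrow(x) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  info <- if ("support" %in% names(x)) paste0("SUPPORT=", x$support) else "."
  body <- paste(x$chrom, format(x$pos, scientific = FALSE, trim = TRUE), ".",
                x$ref, x$alt, ".", ".", info, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Deduplicate sites reported by overlapping windows
#'
#' Joint calling over flanked windows can report the same site from two
#' adjacent windows (once from a core, once from a neighbour's flank). Each
#' site is kept once and attributed to the window whose *core* extent
#' contains its position.
#'
#' @param x A [callset()] (possibly with duplicate rows from per-window
#'   merging; construct with `rbind` of per-window data.frames and
#'   [callset()], which already drops exact duplicates) or a raw data.frame
#'   of sites.
#' @param plan A `bin_plan` covering the callset's chromosomes.
#' @return A [callset()] with one row per site key and a `window_index`
#'   column giving the owning (core) window.
#' @export
dedupe_window_overlap <- function(x, plan) {
  stopifnot(inherits(plan, "bin_plan"))
  sites <- as.data.frame(x)
  sites <- sites[!duplicated(sites[, c("chrom", "pos", "ref", "alt")]), , drop = FALSE]
  w <- plan$windows
  idx <- rep(NA_integer_, nrow(sites))
  for (ch in unique(sites$chrom)) {
    sel <- sites$chrom == ch
    wc <- w[w$chrom == ch, , drop = FALSE]
    if (nrow(wc) == 0) next
    p0 <- sites$pos[sel] - 1  # core extents are 0-based half-open
    hit <- findInterval(p0, wc$start)
    ok <- hit >= 1 & p0 < wc$end[pmax(hit, 1)]
    idx[sel][ok] <- wc$index[hit[ok]]
  }
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop("site outside every core window: ", sites$chrom[bad], ":", sites$pos[bad])
  }
  sites$window_index <- idx
  callset(sites, caller_id = if (inherits(x, "callset")) caller_id(x) else "deduped",
          chrom_order = attr(x, "chrom_order"))
}
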