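#' Read a VCF into a genotype matrix plus variant records
#'
#' Parses GT fields (phased `|` and unphased `/` separators both
#' accepted) into alternate-allele dosages. Biallelic SNPs populate the
#' [genotype_matrix()]; records carrying an `SVTYPE` INFO key are routed
#' to a structural-variant table (with per-individual carrier dosages);
#' other multi-allelic or non-SNP records are skipped with a logged
#' count. SnpEff-style `ANN` annotations are reduced to the effect term
#' of the first annotation (second pipe-delimited field).
#'
#' @param path path to an uncompressed or gzipped VCF with GT
#' @param region optional `"chrom:start-end"` filter
#' @param site_map optional data frame `id`, `site_id` assigning samples
#'   to sites; defaults to one pseudo-site for all samples
#' @return list with `genotypes` (a `genotype_matrix`), `sv` (list of
#'   `records` and `carriers`), `n_skipped` (non-biallelic/non-SNP count)
#' @export
read_vcf <- function(path, region = NULL, site_map = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("no records in VCF: ", path)
  fix$POS <- as.numeric(fix$POS)
  keep_region <- rep(TRUE, nrow(fix))
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4) stop("region must look like chrom:start-end")
    keep_region <- fix$CHROM == m[2] & fix$POS >= as.numeric(m[3]) &
      fix$POS <= as.numeric(m[4])
  }
  info <- fix$INFO %||% rep(".", nrow(fix))
  svtype <- info_field(info, "SVTYPE")
  is_sv <- !is.na(svtype) & keep_region
  single_alt <- !grepl(",", fix$ALT) & !is.na(fix$ALT)
  is_snp <- single_alt & !is_sv &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  keep <- is_snp & keep_region
  n_skipped <- sum(keep_region & !is_snp & !is_sv)
  if (n_skipped > 0) {
    message(sprintf("read_vcf: skipped %d non-biallelic or non-SNP record(s)",
                    n_skipped))
  }

  gt_raw <- vcfR::extract.gt(v, element = "GT")
  dos_all <- gt_to_dosage(gt_raw, fix$POS)
  samples <- colnames(gt_raw)

  loci <- data.frame(chrom = fix$CHROM[keep], pos = fix$POS[keep],
                     ref = fix$REF[keep], alt = fix$ALT[keep],
                     effect = ann_effect(info[keep]),
                     stringsAsFactors = FALSE)
  if (is.null(site_map)) {
    site_map <- data.frame(id = samples, site_id = "all",
                           stringsAsFactors = FALSE)
  }
  ind <- data.frame(id = samples,
                    site_id = site_map$site_id[match(samples, site_map$id)],
                    stringsAsFactors = FALSE)
  gm <- genotype_matrix(t(dos_all[keep, , drop = FALSE]), loci, ind)

  sv_rec <- data.frame(id = fix$ID[is_sv], chrom = fix$CHROM[is_sv],
                       pos = fix$POS[is_sv],
                       sv_type = svtype[is_sv],
                       sv_len = suppressWarnings(
                         as.numeric(info_field(info[is_sv], "SVLEN"))),
                       mate_id = info_field(info[is_sv], "MATEID"),
                       stringsAsFactors = FALSE)
  bad_len <- sv_rec$sv_type %in% c("INS", "DEL", "DUP") & is.na(sv_rec$sv_len)
  if (any(bad_len)) stop("SV record(s) missing SVLEN: ",
                         paste(sv_rec$id[bad_len], collapse = ", "))
  carriers <- t(dos_all[is_sv, , drop = FALSE])
  colnames(carriers) <- sv_rec$id
  list(genotypes = gm,
       sv = list(records = sv_rec, carriers = carriers),
       n_skipped = n_skipped)
}

#' @keywords internal
#' @noRd
gt_to_dosage <- function(gt, pos) {
  d <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  g <- gsub("\\|", "/", gt)
  g <- sub(":.*$", "", g)   # tolerate GT:... payloads leaking through
  d[g %in% c("0/0")] <- 0
  d[g %in% c("0/1", "1/0")] <- 1
  d[g %in% c("1/1")] <- 2
  miss <- is.na(g) | g %in% c("./.", ".")
  bad <- !miss & is.na(d) & !grepl("^[0-9]+/[0-9]+$", g)
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("malformed GT '%s' at record pos %s (sample %s)",
                 gt[bad][1], pos[i[1]], colnames(gt)[i[2]]))
  }
  # multi-allelic calls (e.g. 1/2) stay NA here; such records are skipped
  d
}

#' @keywords internal
#' @noRd
info_field <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]+)")
  m <- regmatches(info, regexec(pat, info))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
         character(1))
}

#' @keywords internal
#' @noRd
ann_effect <- function(info) {
  ann <- info_field(info, "ANN")
  vapply(ann, function(a) {
    if (is.na(a)) return(NA_character_)
    first <- strsplit(a, ",", fixed = TRUE)[[1]][1]
    f <- strsplit(first, "|", fixed = TRUE)[[1]]
    if (length(f) >= 2) f[2] else NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' Write a genotype matrix as a minimal VCF 4.2
#'
#' Emits plain-text VCF with GT-only genotypes; round-trips through
#' [read_vcf()] preserving chrom, pos and dosages.
#'
#' @param gm a [genotype_matrix()]
#' @param path output path
#' @param sv optional SV table (`records` data frame as in [read_vcf()],
#'   plus `carriers`) appended as symbolic-allele records
#' @return `path`, invisibly
#' @export
write_vcf <- function(gm, path, sv = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=streamscape",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
               '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="SV length">',
               '##INFO=<ID=MATEID,Number=1,Type=String,Description="Mate id">',
               '##INFO=<ID=ANN,Number=.,Type=String,Description="Annotation">'),
             con)
  ids <- gm$individuals$id
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", ids), collapse = "\t"), con)
  code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", nrow(gm$dosage), ncol(gm$dosage))
  obs <- !is.na(gm$dosage)
  gt[obs] <- code[as.character(gm$dosage[obs])]
  ref <- gm$loci$ref %||% rep("A", ncol(gm$dosage))
  alt <- gm$loci$alt %||% rep("T", ncol(gm$dosage))
  info <- ifelse(is.na(gm$loci$effect %||% rep(NA, ncol(gm$dosage))), ".",
                 paste0("ANN=T|", gm$loci$effect, "|MODIFIER|gene1"))
  lines <- paste(gm$loci$chrom, gm$loci$pos,
                 paste0("snp", seq_len(ncol(gm$dosage))),
                 ref, alt, ".", "PASS", info, "GT",
                 apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  if (!is.null(sv) && nrow(sv$records)) {
    r <- sv$records
    inf <- paste0("SVTYPE=", r$sv_type,
                  ifelse(is.na(r$sv_len), "", paste0(";SVLEN=", r$sv_len)),
                  ifelse(is.na(r$mate_id), "", paste0(";MATEID=", r$mate_id)))
    cg <- matrix("./.", nrow(sv$carriers), ncol(sv$carriers))
    obs <- !is.na(sv$carriers)
    cg[obs] <- code[as.character(sv$carriers[obs])]
    writeLines(paste(r$chrom, r$pos, r$id, "N",
                     ifelse(r$sv_type == "BND", "N]chr:1]",
                            paste0("<", r$sv_type, ">")),
                     ".", "PASS", inf, "GT",
                     apply(cg, 2, paste, collapse = "\t"), sep = "\t"), con)
  }
  invisible(path)
}

#' Read a site metadata table
#'
#' Tab-separated with header: `site_id`, `metapopulation`, `edge_id`,
#' `offset_km`, `intermittent`, `above_dam`, `reservoir_adjacent`,
#' `cover_developed`, `cover_grassland`, `cover_cropland`, `cover_forest`.
#' Booleans accept 0/1/true/false. Offsets are validated against edge
#' lengths when a network is supplied.
#'
#' @param path TSV path
#' @param network optional [river_network()] for offset validation
#' @return data frame of site records, one per row, input order preserved
#' @export
read_site_table <- function(path, network = NULL) {
  s <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                  stringsAsFactors = FALSE)
  req <- c("site_id", "metapopulation", "edge_id", "offset_km",
           "intermittent", "above_dam", "reservoir_adjacent",
           "cover_developed", "cover_grassland", "cover_cropland",
           "cover_forest")
  miss <- setdiff(req, names(s))
  if (length(miss)) stop("site table missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(s$site_id)) {
    stop("duplicate site_id: ",
         paste(unique(s$site_id[duplicated(s$site_id)]), collapse = ", "))
  }
  for (cc in c("intermittent", "above_dam", "reservoir_adjacent")) {
    s[[cc]] <- parse_bool(s[[cc]])
  }
  cov <- as.matrix(s[, grep("^cover_", names(s))])
  if (any(cov < 0 | cov > 1)) {
    bad <- s$site_id[rowSums(cov < 0 | cov > 1) > 0]
    stop("cover fraction outside [0, 1] for site(s): ",
         paste(bad, collapse = ", "))
  }
  if (!is.null(network)) s <- place_sites(network, s)
  s
}

#' Read a river-network edge list
#'
#' Tab-separated with header matching [river_network()] columns;
#' `to_node` is the downstream node of each edge.
#'
#' @param path TSV path
#' @return a validated [river_network()]
#' @export
read_network <- function(path) {
  e <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                  stringsAsFactors = FALSE)
  river_network(e)
}

#' Write a river-network edge list
#' @param network a [river_network()]
#' @param path TSV path
#' @return `path`, invisibly
#' @export
write_network <- function(network, path) {
  write.table(network$edges, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a site table
#' @param sites site data frame
#' @param path TSV path
#' @return `path`, invisibly
#' @export
write_site_table <- function(sites, path) {
  write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
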