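## Four-table relational store (embedded SQLite): snp_info, gene_info,
## snp_region, TFBS_results. Referential integrity is enforced at build
## time; exports use a fixed row ordering (chrom, pos, pwm, offset) so that
## identical inputs produce byte-identical files.

DB_TABLES <- c("snp_info", "gene_info", "snp_region", "TFBS_results")

#' Build the four-table rSNP database
#'
#' Materializes one pipeline run into an SQLite file with exactly four
#' tables: `snp_info` (SNP records plus the rSNP flag), `gene_info` (gene
#' records), `snp_region` (SNP-to-promoter links with signed distance to the
#' TSS), and `TFBS_results` (per-site consequence records). Referential
#' integrity is checked before writing: every link must reference an
#' existing SNP and gene, and every consequence row must reference an
#' existing SNP and join to at least one link whose gene lies on the row's
#' strand. `no_change` records are excluded by default — the results table
#' stores the consequences of rSNPs — and retained with
#' `keep_no_change = TRUE`.
#'
#' @param snps,genes,links,consequences data.frames from one pipeline run
#'   ([read_snp_catalog()], [read_gene_annotations()], [assign_snps()],
#'   [annotate_consequences()]).
#' @param path SQLite file path, or `":memory:"`.
#' @param keep_no_change Store `no_change` rows too.
#' @return An `RsnpDatabase` handle (list with the DBI connection and the
#'   build-window extents). Close with [close_database()].
#' @export
build_database <- function(snps, genes, links, consequences,
                           path = ":memory:", keep_no_change = FALSE) {
  dup_snp <- unique(snps$snp_id[duplicated(snps$snp_id)])
  if (length(dup_snp)) {
    stop_rsnpdb("integrity error: duplicate snp_id: ",
                paste(utils::head(dup_snp, 5), collapse = ", "))
  }
  dup_gene <- unique(genes$gene_id[duplicated(genes$gene_id)])
  if (length(dup_gene)) {
    stop_rsnpdb("integrity error: duplicate gene_id: ",
                paste(utils::head(dup_gene, 5), collapse = ", "))
  }
  bad <- setdiff(links$snp_id, snps$snp_id)
  if (length(bad)) {
    stop_rsnpdb("integrity error: snp_region references unknown snp_id: ",
                bad[1])
  }
  bad <- setdiff(links$gene_id, genes$gene_id)
  if (length(bad)) {
    stop_rsnpdb("integrity error: snp_region references unknown gene_id: ",
                bad[1])
  }
  dup_link <- duplicated(paste(links$snp_id, links$gene_id))
  if (any(dup_link)) {
    stop_rsnpdb("integrity error: duplicate snp_region row for (",
                links$snp_id[dup_link][1], ", ", links$gene_id[dup_link][1], ")")
  }
  if (!keep_no_change && nrow(consequences)) {
    consequences <- consequences[consequences$consequence != "no_change", ,
                                 drop = FALSE]
  }
  bad <- setdiff(consequences$snp_id, snps$snp_id)
  if (length(bad)) {
    stop_rsnpdb("integrity error: TFBS_results references unknown snp_id: ",
                bad[1])
  }
  if (nrow(consequences)) {
    strand_of <- setNames(genes$strand, genes$gene_id)
    link_ctx <- unique(paste(links$snp_id, unname(strand_of[links$gene_id])))
    ctx <- paste(consequences$snp_id, consequences$gene_strand)
    orphan <- !ctx %in% link_ctx
    if (any(orphan)) {
      stop_rsnpdb("integrity error: TFBS_results row for (",
                  consequences$snp_id[orphan][1], ", strand ",
                  consequences$gene_strand[orphan][1],
                  ") joins to no snp_region row")
    }
  }
  flags <- flag_rsnps(consequences, snp_ids = snps$snp_id)
  snp_info <- merge(snps, flags, by = "snp_id", sort = FALSE)
  snp_info <- snp_info[order(snp_info$chrom, snp_info$pos, snp_info$snp_id), ,
                       drop = FALSE]
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  DBI::dbExecute(con, paste(
    "CREATE TABLE snp_info (snp_id TEXT PRIMARY KEY, chrom TEXT, pos INTEGER,",
    "ref_allele TEXT, alt_allele TEXT, is_rsnp INTEGER, n_affected_tfbs INTEGER)"))
  DBI::dbExecute(con, paste(
    "CREATE TABLE gene_info (gene_id TEXT PRIMARY KEY, name TEXT, chrom TEXT,",
    "strand TEXT, tss INTEGER, start INTEGER, end INTEGER, source_feature TEXT)"))
  DBI::dbExecute(con, paste(
    "CREATE TABLE snp_region (snp_id TEXT REFERENCES snp_info(snp_id),",
    "gene_id TEXT REFERENCES gene_info(gene_id), distance_to_tss INTEGER,",
    "PRIMARY KEY (snp_id, gene_id))"))
  DBI::dbExecute(con, paste(
    "CREATE TABLE TFBS_results (snp_id TEXT REFERENCES snp_info(snp_id),",
    "gene_strand TEXT, pwm_id TEXT, seq_offset INTEGER, orientation TEXT,",
    "consequence TEXT, ref_core_score REAL, ref_matrix_score REAL,",
    "alt_core_score REAL, alt_matrix_score REAL, ref_site_seq TEXT,",
    "alt_site_seq TEXT)"))
  snp_info$is_rsnp <- as.integer(snp_info$is_rsnp)
  DBI::dbWriteTable(con, "snp_info", snp_info, append = TRUE)
  DBI::dbWriteTable(con, "gene_info",
                    genes[order(genes$chrom, genes$tss, genes$gene_id), ,
                          drop = FALSE], append = TRUE)
  ld <- as.data.frame(links)[, c("snp_id", "gene_id", "distance_to_tss")]
  DBI::dbWriteTable(con, "snp_region", ld, append = TRUE)
  DBI::dbWriteTable(con, "TFBS_results", as.data.frame(consequences),
                    append = TRUE)
  db <- structure(
    list(con = con, path = path,
         built_upstream_bp = attr(links, "upstream_bp") %||% 7500,
         built_downstream_bp = attr(links, "downstream_bp") %||% 2500),
    class = "RsnpDatabase")
  db
}

#' Open an existing rSNP database file
#'
#' @param path SQLite file created by [build_database()].
#' @param built_upstream_bp,built_downstream_bp Window extents the database
#'   was built with (defaults 7500 / 2500); used to validate query windows.
#' @return `RsnpDatabase` handle.
#' @export
open_database <- function(path, built_upstream_bp = 7500,
                          built_downstream_bp = 2500) {
  if (!file.exists(path)) stop_rsnpdb("database file not found: ", path)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  tabs <- DBI::dbListTables(con)
  if (!all(DB_TABLES %in% tabs)) {
    DBI::dbDisconnect(con)
    stop_rsnpdb("not an rSNP database (missing tables): ", path)
  }
  structure(list(con = con, path = path,
                 built_upstream_bp = built_upstream_bp,
                 built_downstream_bp = built_downstream_bp),
            class = "RsnpDatabase")
}

#' Close an rSNP database handle
#' @param db `RsnpDatabase`.
#' @return `NULL`, invisibly.
#' @export
close_database <- function(db) {
  DBI::dbDisconnect(db$con)
  invisible(NULL)
}

#' @export
print.RsnpDatabase <- function(x, ...) {
  cat("RsnpDatabase", x$path, "\n")
  for (t in db_tables(x)) {
    n <- DBI::dbGetQuery(x$con, paste0("SELECT COUNT(*) AS n FROM ", t))$n
    cat(sprintf("  %-13s %d rows\n", t, n))
  }
  invisible(x)
}

#' List the tables of an rSNP database
#' @param db `RsnpDatabase`.
#' @return Character vector of table names.
#' @export
db_tables <- function(db) {
  DBI::dbListTables(db$con)
}

#' Row counts of the four tables
#' @param db `RsnpDatabase`.
#' @return Named integer vector over the four tables.
#' @export
db_counts <- function(db) {
  vapply(DB_TABLES, function(t) {
    as.integer(DBI::dbGetQuery(db$con, paste0("SELECT COUNT(*) AS n FROM ", t))$n)
  }, integer(1))
}

## Internal: fully joined result rows (snp_region x gene_info x snp_info x
## TFBS_results on snp_id + gene strand), optionally restricted to a set of
## snp ids, then window-filtered.
joined_results <- function(db, snp_ids = NULL, upstream_bp = 1000,
                           downstream_bp = 100) {
  if (upstream_bp > db$built_upstream_bp ||
      downstream_bp > db$built_downstream_bp) {
    stop_rsnpdb(sprintf(
      "requested window (-%d/+%d) exceeds the built window (-%d/+%d)",
      upstream_bp, downstream_bp, db$built_upstream_bp, db$built_downstream_bp))
  }
  sql <- paste(
    "SELECT s.snp_id, s.chrom, s.pos, s.ref_allele, s.alt_allele,",
    "       r.gene_id, g.name AS gene_name, g.strand AS gene_strand,",
    "       r.distance_to_tss, t.pwm_id, t.seq_offset, t.orientation,",
    "       t.consequence, t.ref_core_score, t.ref_matrix_score,",
    "       t.alt_core_score, t.alt_matrix_score, t.ref_site_seq,",
    "       t.alt_site_seq",
    "FROM snp_region r",
    "JOIN snp_info s ON s.snp_id = r.snp_id",
    "JOIN gene_info g ON g.gene_id = r.gene_id",
    "JOIN TFBS_results t ON t.snp_id = r.snp_id AND t.gene_strand = g.strand",
    "WHERE r.distance_to_tss >= ? AND r.distance_to_tss <= ?")
  params <- list(-upstream_bp, downstream_bp)
  if (!is.null(snp_ids)) {
    sql <- paste0(sql, " AND s.snp_id IN (",
                  paste(rep("?", length(snp_ids)), collapse = ","), ")")
    params <- c(params, as.list(snp_ids))
  }
  sql <- paste(sql, "ORDER BY s.chrom, s.pos, s.snp_id, r.gene_id,",
               "t.pwm_id, t.seq_offset, t.orientation")
  res <- DBI::dbGetQuery(db$con, sql, params = params)
  res$ref_bound <- res$consequence %in% c("loss", "score_change", "no_change")
  res$alt_bound <- res$consequence %in% c("gain", "score_change", "no_change")
  res
}

#' Query the database for binding-site consequences
#'
#' Four query modes, mirroring the search facilities of the web front end
#' this store replaces: by SNP identifiers (a character vector or one
#' whitespace-separated string; the union without duplicates is returned),
#' by exact SNP position, by chromosomal region (`"chrom:start-end"`,
#' 1-based inclusive), or by gene (id or name). All modes re-filter the
#' SNP-promoter links to the user window (default -1 kb / +100 bp) before
#' joining the consequence rows.
#'
#' @param db `RsnpDatabase`.
#' @param mode One of `"snp_ids"`, `"position"`, `"region"`, `"gene"`.
#' @param query Mode argument: ids string/vector; `c(chrom, pos)`;
#'   `"chrom:start-end"`; gene id or name.
#' @param upstream_bp,downstream_bp User promoter window (defaults
#'   1000 / 100); must not exceed the built window.
#' @return data.frame of joined result rows (one per SNP-gene-site), with
#'   per-allele scores, site sequences, consequence and binding-site
#'   presence per allele. Unknown ids or genes yield an empty result with a
#'   warning.
#' @export
query_database <- function(db, mode = c("snp_ids", "position", "region", "gene"),
                           query, upstream_bp = 1000, downstream_bp = 100) {
  mode <- match.arg(mode)
  ids <- switch(
    mode,
    snp_ids = {
      ids <- unique(unlist(strsplit(as.character(query), "\\s+")))
      ids <- ids[ids != ""]
      known <- DBI::dbGetQuery(
        db$con,
        paste0("SELECT snp_id FROM snp_info WHERE snp_id IN (",
               paste(rep("?", length(ids)), collapse = ","), ")"),
        params = as.list(ids))$snp_id
      if (length(known) < length(ids)) {
        warning("unknown SNP id(s): ",
                paste(setdiff(ids, known), collapse = ", "), call. = FALSE)
      }
      known
    },
    position = {
      DBI::dbGetQuery(db$con,
                      "SELECT snp_id FROM snp_info WHERE chrom = ? AND pos = ?",
                      params = list(query[[1]], as.integer(query[[2]])))$snp_id
    },
    region = {
      m <- regmatches(query, regexec("^([^:]+):([0-9]+)-([0-9]+)$", query))[[1]]
      if (length(m) != 4) {
        stop_rsnpdb("region must be 'chrom:start-end', got: ", query)
      }
      DBI::dbGetQuery(
        db$con,
        "SELECT snp_id FROM snp_info WHERE chrom = ? AND pos >= ? AND pos <= ?",
        params = list(m[2], as.integer(m[3]), as.integer(m[4])))$snp_id
    },
    gene = {
      snp <- DBI::dbGetQuery(
        db$con,
        paste("SELECT r.snp_id FROM snp_region r JOIN gene_info g",
              "ON g.gene_id = r.gene_id WHERE g.gene_id = ? OR g.name = ?"),
        params = list(query, query))$snp_id
      if (length(snp) == 0) {
        warning("unknown gene or gene without promoter SNPs: ", query,
                call. = FALSE)
      }
      unique(snp)
    }
  )
  if (length(ids) == 0) {
    return(joined_results(db, snp_ids = "\r__none__",
                          upstream_bp = upstream_bp,
                          downstream_bp = downstream_bp))
  }
  res <- joined_results(db, snp_ids = ids, upstream_bp = upstream_bp,
                        downstream_bp = downstream_bp)
  if (mode == "gene") res <- res[res$gene_id == query | res$gene_name %in% query, ,
                                 drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Export TFBS results as TSV, optionally chromosome-wise
#'
#' Rows are ordered by (chrom, pos, snp_id, gene, pwm, offset, orientation),
#' so rebuilding the database from identical inputs yields byte-identical
#' exports. Site sequences keep the core uppercase convention and mark the
#' SNP base with brackets (e.g. `aat[A]aT`), the text rendering of the
#' highlighted SNP position.
#'
#' The union of all per-chromosome exports equals the full results table.
#'
#' @param db `RsnpDatabase`.
#' @param path Output TSV path.
#' @param chrom Restrict to one chromosome (default: all).
#' @param upstream_bp,downstream_bp Window applied before export; defaults
#'   to the full built window so the export covers the whole table.
#' @return `path`, invisibly.
#' @export
export_results <- function(db, path, chrom = NULL,
                           upstream_bp = db$built_upstream_bp,
                           downstream_bp = db$built_downstream_bp) {
  res <- joined_results(db, upstream_bp = upstream_bp,
                        downstream_bp = downstream_bp)
  if (!is.null(chrom)) res <- res[res$chrom == chrom, , drop = FALSE]
  pwm_w <- nchar(res$ref_site_seq)
  pwm_w[is.na(pwm_w)] <- nchar(res$alt_site_seq)[is.na(pwm_w)]
  res$ref_site_seq <- mark_snp_base(res$ref_site_seq, res$seq_offset,
                                    res$orientation, pwm_w)
  res$alt_site_seq <- mark_snp_base(res$alt_site_seq, res$seq_offset,
                                    res$orientation, pwm_w)
  write_tsv_det(res, path)
}

## Internal: bracket the SNP base inside a site string. site strings are in
## PWM orientation; for forward matches the SNP sits at string position
## 26 - offset + 1, for reverse matches at offset + width - 26 (footprints
## always cover position 26 after restrict_to_snp_overlap).
mark_snp_base <- function(site, offset, orientation, width) {
  out <- character(length(site))
  for (i in seq_along(site)) {
    if (is.na(site[i])) { out[i] <- NA_character_; next }
    p <- if (orientation[i] == "forward") CENTER_POS - offset[i] + 1L
         else offset[i] + width[i] - CENTER_POS
    if (p < 1L || p > nchar(site[i])) { out[i] <- site[i]; next }
    out[i] <- paste0(substr(site[i], 1L, p - 1L), "[",
                     substr(site[i], p, p), "]",
                     substr(site[i], p + 1L, nchar(site[i])))
  }
  out
}

#' Summary statistics of an rSNP database
#'
#' Computed within the given promoter window (default -1 kb / +100 bp):
#' number of distinct promoter SNPs and rSNPs in the window, rSNPs per
#' promoter averaged over all annotated genes (genes without promoter SNPs
#' contribute zero), the percentage of promoter SNPs that are rSNPs, the
#' mean number of affected binding sites per rSNP, and the histogram of
#' rSNP-to-TSS distances in 50-bp bins over the proximal promoter
#' (left-closed right-open bins on `[-750, +250)`).
#'
#' @param db `RsnpDatabase`.
#' @param upstream_bp,downstream_bp Window; must not exceed the built one.
#' @return List of class `SummaryStats`: `n_snps`, `n_genes`, `n_rsnps`,
#'   `rsnps_per_promoter`, `pct_rsnp`, `tfbs_per_rsnp`, `tss_histogram`
#'   (named integer vector of bin counts). An empty database yields all
#'   zeros.
#' @export
summarize_database <- function(db, upstream_bp = 1000, downstream_bp = 100) {
  if (upstream_bp > db$built_upstream_bp ||
      downstream_bp > db$built_downstream_bp) {
    stop_rsnpdb(sprintf(
      "requested window (-%d/+%d) exceeds the built window (-%d/+%d)",
      upstream_bp, downstream_bp, db$built_upstream_bp, db$built_downstream_bp))
  }
  links <- DBI::dbGetQuery(
    db$con,
    paste("SELECT r.snp_id, r.gene_id, r.distance_to_tss, s.is_rsnp",
          "FROM snp_region r JOIN snp_info s ON s.snp_id = r.snp_id",
          "WHERE r.distance_to_tss >= ? AND r.distance_to_tss <= ?"),
    params = list(-upstream_bp, downstream_bp))
  n_genes <- DBI::dbGetQuery(db$con, "SELECT COUNT(*) AS n FROM gene_info")$n
  n_snps <- length(unique(links$snp_id))
  rlinks <- links[links$is_rsnp == 1L, , drop = FALSE]
  n_rsnps <- length(unique(rlinks$snp_id))
  per_gene <- table(rlinks$gene_id)
  rsnps_per_promoter <- if (n_genes > 0) sum(per_gene) / n_genes else 0
  pct_rsnp <- if (n_snps > 0) 100 * n_rsnps / n_snps else 0
  tfbs_per_rsnp <- if (n_rsnps > 0) {
    aff <- DBI::dbGetQuery(
      db$con,
      paste("SELECT n_affected_tfbs FROM snp_info WHERE is_rsnp = 1",
            "AND snp_id IN (", paste(rep("?", n_rsnps), collapse = ","), ")"),
      params = as.list(unique(rlinks$snp_id)))
    mean(aff$n_affected_tfbs)
  } else 0
  breaks <- seq(-750L, 250L, by = 50L)
  bin_lab <- paste0("[", breaks[-length(breaks)], ",", breaks[-1], ")")
  hist_counts <- setNames(integer(length(bin_lab)), bin_lab)
  d <- rlinks$distance_to_tss
  d <- d[d >= -750 & d < 250]
  if (length(d)) {
    bins <- findInterval(d, breaks, rightmost.closed = FALSE)
    tb <- table(bins)
    hist_counts[as.integer(names(tb))] <- as.integer(tb)
  }
  structure(list(n_snps = n_snps, n_genes = n_genes, n_rsnps = n_rsnps,
                 rsnps_per_promoter = rsnps_per_promoter,
                 pct_rsnp = pct_rsnp, tfbs_per_rsnp = tfbs_per_rsnp,
                 tss_histogram = hist_counts),
            class = "SummaryStats")
}

#' @export
print.SummaryStats <- function(x, ...) {
  cat(sprintf("promoter SNPs: %d  rSNPs: %d (%.2f%%)\n",
              x$n_snps, x$n_rsnps, x$pct_rsnp))
  cat(sprintf("genes: %d  rSNPs per promoter: %.4f  TFBSs per rSNP: %.4f\n",
              x$n_genes, x$rsnps_per_promoter, x$tfbs_per_rsnp))
  cat("TSS-distance histogram (50-bp bins, [-750,+250)):\n")
  print(x$tss_histogram)
  invisible(x)
}
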