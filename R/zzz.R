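#' @importFrom data.table data.table as.data.table setattr setorder fread
#'   fwrite rbindlist setkey setcolorder copy :=
NULL

.datatable.aware <- TRUE

# data.table non-standard-evaluation column names
utils::globalVariables(c(
  ".", ".N", ".SD", "gene_id", "group", "conservation_index",
  "n_missense", "n_nonsense", "n_fs", "n_silent", "density_missense",
  "density_nonsense", "density_fs", "density_silent", "chrom", "pos",
  "value", "start", "end", "replication_time", "n_silent_observed",
  "snp_density", "n_unique_snps", "cds_length", "t", "max_z",
  "z_missense", "z_nonsense", "z_fs", "mean_expression",
  "log_mean_expression", "chromatin_accessibility", "mutsig_expr",
  "mutsig_hic", "mutsig_reptime", "is_driver", "driver_class", "snp",
  "screen", "sample_id"))
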