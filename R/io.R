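#' Write a trajectory as delimited text with a metadata header
#'
#' One row per output sample; columns `time` (s), node potentials, RP along
#' the dendrite, `RP_b`, `RP_s`, `SP` and, when present, the lumped
#' conductances. Metadata (N, solver-independent parameters, package
#' version, run id) is recorded in `#`-prefixed header lines.
#'
#' @param traj A `sensillum_trajectory`.
#' @param file Output path.
#' @param digits Significant digits used for floating output.
#' @return `file`, invisibly.
#' @export
write_trajectory <- function(traj, file, digits = 12) {
  sc <- traj$scaling
  hdr <- c(
    paste0("# sensillum trajectory, package version ",
           as.character(utils::packageVersion("sensillum"))),
    paste0("# N = ", sc$N, ", E_p = ", traj$E_p, " mV"),
    paste0("# g_ldc = ", signif(sc$g_ldc, 6), " nS, g_ec = ",
           signif(sc$g_ec, 6), " nS, g_ic = ", signif(sc$g_ic, 6), " nS"),
    paste0("# run id = ", format(Sys.time(), "%Y%m%dT%H%M%S"), "-",
           substr(digest_params(sc), 1, 8))
  )
  df <- data.frame(time = traj$time)
  for (j in seq_len(sc$N)) {
    df[[paste0("V_id_", j)]] <- traj$V_id[, j]
    df[[paste0("V_ed_", j)]] <- traj$V_ed[, j]
  }
  df$V_is <- traj$V_is
  df$V_a <- traj$V_a
  for (j in seq_len(sc$N)) df[[paste0("RP_", j)]] <- traj$RP[, j]
  df$RP_b <- traj$RP_b
  df$RP_s <- traj$RP_s
  df$SP <- traj$SP
  if (!is.null(traj$g_p)) {
    for (j in seq_len(sc$N)) df[[paste0("g_p_", j)]] <- traj$g_p[, j]
  }
  df[] <- lapply(df, function(x) signif(x, digits))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

# deterministic content hash of the numeric parameters (no external deps)
digest_params <- function(scaling) {
  v <- unlist(scaling$derived[!vapply(scaling$derived, is.list, logical(1))])
  s <- paste(sprintf("%.10e", c(scaling$N, v)), collapse = ",")
  r <- as.numeric(utf8ToInt(s))
  h <- c(17, 23, 5, 31)
  for (i in seq_along(r)) {
    k <- (i %% 4) + 1
    h[k] <- (h[k] * 131 + r[i]) %% 1000000007
  }
  paste(sprintf("%08x", as.integer(h)), collapse = "")
}

#' Derived-parameter table as a data.frame
#'
#' Tabulates every derived cable/circuit quantity with symbol, unit and
#' value, in the layout used for reporting and by the command-line
#' `derive-params` command.
#'
#' @param derived A `sensillum_derived` object.
#' @return data.frame with columns `symbol`, `unit`, `value`.
#' @export
derived_param_table <- function(derived) {
  rows <- list(
    c("S_d", "um^2"), c("V_d", "um^3"), c("E_ld", "mV"), c("c_d", "F/cm"),
    c("C_d", "pF"), c("r_ld", "MOhm.cm"), c("R_ld", "GOhm"), c("G_ld", "nS"),
    c("lambda", "um"), c("tau", "ms"), c("l_d", "-"),
    c("r_e", "GOhm/cm"), c("g_e", "nS.cm"), c("R_e", "MOhm"), c("G_e", "nS"),
    c("r_i", "GOhm/cm"), c("g_i", "nS.cm"), c("R_i", "MOhm"), c("G_i", "nS"),
    c("R_ls", "MOhm"), c("G_ls", "nS"), c("C_s", "pF"),
    c("r_in", "-"), c("a", "-"),
    c("S_api", "um^2"), c("rho_api", "Ohm.cm^2"), c("S_bas", "um^2"),
    c("C_bas", "pF"), c("R_a", "MOhm"), c("G_a", "nS"), c("C_a", "pF"))
  data.frame(
    symbol = vapply(rows, `[`, "", 1L),
    unit = vapply(rows, `[`, "", 2L),
    value = vapply(rows, function(r) derived[[r[1L]]], numeric(1)))
}
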