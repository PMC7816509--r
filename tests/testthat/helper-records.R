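# Build a single lab record with sensible defaults, overridable per field.
lab_record <- function(net_id = "netX", brand = "BX", bursting_kpa = 350,
                       snag_n = 100, abrasion_rubs = 200, end_hole_mm = 3,
                       secondary_damage = "none") {
  list(net_id = net_id, brand = brand, bursting_kpa = bursting_kpa,
       snag_n = snag_n, abrasion_rubs = abrasion_rubs,
       end_hole_mm = end_hole_mm, secondary_damage = secondary_damage)
}

lab_panel_df <- function(...) {
  recs <- list(...)
  out <- do.call(rbind, lapply(recs, function(r) as.data.frame(r)))
  class(out) <- c("lab_panel", "data.frame")
  out
}

write_lab_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  header <- "net_id,brand,bursting_kpa,snag_n,abrasion_rubs,end_hole_mm,secondary_damage"
  writeLines(c(header, lines), path)
  path
}
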