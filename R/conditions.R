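# Classed error conditions so callers (and the CLI) can distinguish user
# errors from internal ones.

abort_anchor <- function(message, class) {
  stop(structure(
    class = c(class, "anchor3d_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

# user-facing error classes; anything else escaping run_cli() is internal
ANCHOR3D_USER_ERRORS <- c(
  "anchor3d_parameter_error", "anchor3d_annotation_error",
  "anchor3d_degeneracy_error", "anchor3d_geometry_error",
  "anchor3d_build_error", "anchor3d_topology_error",
  "anchor3d_lookup_error", "anchor3d_table_error",
  "anchor3d_parse_error", "anchor3d_io_error", "anchor3d_usage_error"
)
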