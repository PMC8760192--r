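# Regenerates the shipped default registry YAML files from the in-code
# defaults. Run from the package root after editing R/registry.R:
#   Rscript tools/make_registries.R
pkgload::load_all(".", quiet = TRUE)
write_registry(default_registry("in_vivo"), "inst/registries/nmp_tsat_invivo_v1.yaml")
write_registry(default_registry("in_vitro"), "inst/registries/nmp_tsat_invitro_v1.yaml")
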