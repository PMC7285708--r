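# Supplementary-table layout

`supplement_stats()` reads TSV exports of the article's
supplementary spreadsheets from this directory. The tables are
distributed with the article and are not redistributed here. Expected
files (tab-separated, with header):

- `table_s1.tsv` — sample_id, core, depth_cm, pH, EC, TOC, TP, TS,
  Fe2_TFe, SO4_TS, metal columns, votu_richness, otu_richness
- `table_s3_coverage.tsv` — votu_id, family ("unclassified" when
  unaffiliated), one normalized-coverage column per sample_id
- `table_s4_otus.tsv` — otu_id, phylum, one count column per sample_id
- `table_s5_prophages.tsv` — viral_id (one row per prophage; ids must
  match the ids used in table S3)
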