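# Synthetic reconstruction of an elongation-factor presence/absence survey
# across eukaryotes (eEF1A, its GEF subunit eEF1Ba, and the paralog EFL).
# States: present / divergent (detectable but decaying) / absent.
# This is NOT the original supplementary survey table; it encodes the
# distribution pattern the survey describes, with explicitly reported species
# states reproduced and the remaining rows filled from the well-established
# EFL/eEF1A distribution across major lineages.
taxon	lineage	eEF1A	eEF1Ba	EFL
Homo_sapiens	Metazoa	present	present	absent
Mus_musculus	Metazoa	present	present	absent
Danio_rerio	Metazoa	present	present	absent
Drosophila_melanogaster	Metazoa	present	present	absent
Caenorhabditis_elegans	Metazoa	present	present	absent
Nematostella_vectensis	Metazoa	present	present	absent
Amphimedon_queenslandica	Metazoa	present	present	absent
Monosiga_brevicollis	Choanoflagellatea	absent	absent	present
Salpingoeca_rosetta	Choanoflagellatea	absent	absent	present
Monosiga_sp_ATCC50635	Choanoflagellatea	present	present	absent
Sphaeroforma_arctica	Ichthyosporea	absent	absent	present
Capsaspora_owczarzaki	Filasterea	present	present	absent
Saccharomyces_cerevisiae	Fungi	present	present	absent
Schizosaccharomyces_pombe	Fungi	present	present	absent
Neurospora_crassa	Fungi	present	present	absent
Aspergillus_niger	Fungi	divergent	absent	present
Ustilago_maydis	Fungi	present	present	absent
Cryptococcus_neoformans	Fungi	present	present	absent
Rhizopus_oryzae	Fungi	present	present	absent
Batrachochytrium_dendrobatidis	Fungi	absent	absent	present
Spizellomyces_punctatus	Fungi	absent	absent	present
Allomyces_macrogynus	Fungi	divergent	absent	present
Conidiobolus_coronatus	Fungi	absent	absent	present
Thecamonas_trahens	Apusozoa	present	present	divergent
Dictyostelium_discoideum	Amoebozoa	present	present	absent
Entamoeba_histolytica	Amoebozoa	present	present	absent
Acanthamoeba_castellanii	Amoebozoa	present	present	absent
Arabidopsis_thaliana	Viridiplantae	present	present	absent
Oryza_sativa	Viridiplantae	present	present	absent
Selaginella_moellendorffii	Viridiplantae	present	present	absent
Physcomitrella_patens	Viridiplantae	present	present	absent
Chlorella_variabilis	Viridiplantae	present	present	absent
Chlamydomonas_reinhardtii	Viridiplantae	divergent	absent	present
Volvox_carteri	Viridiplantae	divergent	absent	present
Ostreococcus_tauri	Viridiplantae	absent	absent	present
Ostreococcus_lucimarinus	Viridiplantae	absent	absent	present
Micromonas_pusilla	Viridiplantae	absent	absent	present
Ulva_prolifera	Viridiplantae	present	absent	present
Cyanidioschyzon_merolae	Rhodophyta	absent	absent	present
Galdieria_sulphuraria	Rhodophyta	absent	absent	present
Chondrus_crispus	Rhodophyta	absent	absent	present
Porphyra_yezoensis	Rhodophyta	absent	absent	present
Guillardia_theta	Cryptophyta	present	divergent	present
Emiliania_huxleyi	Haptophyta	present	present	absent
Bigelowiella_natans	Rhizaria	divergent	absent	present
Thalassiosira_pseudonana	Heterokontophyta	present	absent	present
Phaeodactylum_tricornutum	Heterokontophyta	absent	absent	present
Pseudo-nitzschia_multiseries	Heterokontophyta	divergent	absent	present
Fragilariopsis_cylindrus	Heterokontophyta	divergent	absent	present
Aureococcus_anophagefferens	Heterokontophyta	absent	absent	present
Ectocarpus_siliculosus	Heterokontophyta	present	present	absent
Phytophthora_infestans	Oomycetes	absent	absent	present
Phytophthora_sojae	Oomycetes	absent	absent	present
Pythium_ultimum	Oomycetes	absent	divergent	present
Karenia_brevis	Dinophyceae	present	absent	present
Symbiodinium_sp	Dinophyceae	present	absent	present
Alexandrium_tamarense	Dinophyceae	absent	absent	present
Oxyrrhis_marina	Dinophyceae	absent	absent	present
Perkinsus_marinus	Alveolata	absent	absent	present
Tetrahymena_thermophila	Alveolata	present	present	absent
Paramecium_tetraurelia	Alveolata	present	present	absent
Plasmodium_falciparum	Alveolata	present	present	absent
Toxoplasma_gondii	Alveolata	present	present	absent
Cryptosporidium_parvum	Alveolata	present	present	absent
Trypanosoma_brucei	Excavata	present	present	absent
Leishmania_major	Excavata	present	present	absent
Naegleria_gruberi	Excavata	present	present	absent
Giardia_lamblia	Excavata	present	present	absent
Trichomonas_vaginalis	Excavata	present	present	absent
Diplonema_papillatum	Excavata	absent	absent	present
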