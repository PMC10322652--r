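<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic metabocard fixture: no diseases block, corrected monoisotopic
     spelling; not real HMDB data. -->
<metabolite>
  <accession>HMDB0990002</accession>
  <name>Synthoanserine</name>
  <chemical_formula>C10H16N4O3</chemical_formula>
  <average_molecular_weight>240.2600</average_molecular_weight>
  <monoisotopic_molecular_weight>240.1222</monoisotopic_molecular_weight>
  <taxonomy>
    <kingdom>Organic compounds</kingdom>
    <super_class>Organic acids and derivatives</super_class>
    <class>Carboxylic acids and derivatives</class>
    <sub_class>Amino acids, peptides, and analogues</sub_class>
    <substituents>
      <substituent>Imidazolyl carboxylic acid</substituent>
      <substituent>Dipeptide</substituent>
      <substituent>N-methylimidazole</substituent>
    </substituents>
  </taxonomy>
  <biological_properties>
    <pathways>
      <pathway>
        <name>Histidine metabolism</name>
      </pathway>
      <pathway>
        <name>Beta-alanine metabolism</name>
      </pathway>
    </pathways>
  </biological_properties>
  <protein_associations>
    <protein>
      <gene_name>CARNS1</gene_name>
      <name>Carnosine synthase 1</name>
    </protein>
  </protein_associations>
</metabolite>
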