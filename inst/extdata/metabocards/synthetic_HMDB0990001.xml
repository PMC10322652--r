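<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic metabocard fixture in the hmdb.ca v4 layout; not real HMDB data. -->
<metabolite xmlns="http://www.hmdb.ca">
  <accession>HMDB0990001</accession>
  <name>Synthocarnosine</name>
  <synonyms>
    <synonym>beta-Synthocarnosine</synonym>
    <synonym>Synth-His dipeptide</synonym>
  </synonyms>
  <chemical_formula>C9H14N4O3</chemical_formula>
  <average_molecular_weight>146.1451</average_molecular_weight>
  <monisotopic_molecular_weight>146.0691</monisotopic_molecular_weight>
  <smiles>NCCC(=O)NC(Cc1cnc[nH]1)C(=O)O</smiles>
  <taxonomy>
    <kingdom>Organic compounds</kingdom>
    <super_class>Organic acids and derivatives</super_class>
    <class>Carboxylic acids and derivatives</class>
    <sub_class>Amino acids, peptides, and analogues</sub_class>
    <substituents>
      <substituent>Imidazolyl carboxylic acid</substituent>
      <substituent>Dipeptide</substituent>
    </substituents>
  </taxonomy>
  <biological_properties>
    <pathways>
      <pathway>
        <name>Histidine metabolism</name>
      </pathway>
    </pathways>
  </biological_properties>
  <diseases>
    <disease>
      <name>Synthetic myopathy</name>
    </disease>
  </diseases>
  <protein_associations>
    <protein>
      <gene_name>CNDP1</gene_name>
      <name>Beta-Ala-His dipeptidase</name>
    </protein>
  </protein_associations>
</metabolite>
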