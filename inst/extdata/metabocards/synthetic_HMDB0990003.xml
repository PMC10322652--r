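<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic metabocard fixture: minimal card, most blocks absent; not
     real HMDB data. -->
<metabolite>
  <accession>HMDB0990003</accession>
  <name>Synthohexanoate</name>
  <taxonomy>
    <kingdom>Organic compounds</kingdom>
    <super_class>Lipids and lipid-like molecules</super_class>
    <class>Fatty Acyls</class>
    <sub_class>Fatty acids and conjugates</sub_class>
    <substituents>
      <substituent>Carboxylic acid</substituent>
    </substituents>
  </taxonomy>
</metabolite>
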