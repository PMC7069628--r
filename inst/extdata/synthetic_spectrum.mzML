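<?xml version="1.0" encoding="utf-8"?>
<indexedmzML xmlns="http://psi.hupo.org/ms/mzml">
<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0" id="example">
  <cvList count="2">
    <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" version="4.1.0" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>
    <cv id="UO" fullName="Unit Ontology" version="releases/2020-03-10" URI="http://ontologies.berkeleybop.org/uo.obo"/>
  </cvList>
  <fileDescription>
    <fileContent><cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/></fileContent>
  </fileDescription>
  <softwareList count="1"><software id="sw" version="0.1"><cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="synthetic"/></software></softwareList>
  <instrumentConfigurationList count="1"><instrumentConfiguration id="ic"><cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/></instrumentConfiguration></instrumentConfigurationList>
  <dataProcessingList count="1"><dataProcessing id="dp"><processingMethod order="1" softwareRef="sw"><cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/></processingMethod></dataProcessing></dataProcessingList>
  <run id="run1" defaultInstrumentConfigurationRef="ic">
    <spectrumList count="1" defaultDataProcessingRef="dp">
      <spectrum index="0" id="scan=1" defaultArrayLength="100">
        <cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>
        <cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="1"/>
        <cvParam cvRef="MS" accession="MS:1000128" name="profile spectrum" value=""/>
        <binaryDataArrayList count="2">
          <binaryDataArray encodedLength="1068">
            <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>
            <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>
            <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>
            <binary>AAAAAABAn0AAAAAAAFCfQAAAAAAAYJ9AAAAAAABwn0AAAAAAAICfQAAAAAAAkJ9AAAAAAACgn0AAAAAAALCfQAAAAAAAwJ9AAAAAAADQn0AAAAAAAOCfQAAAAAAA8J9AAAAAAAAAoEAAAAAAAAigQAAAAAAAEKBAAAAAAAAYoEAAAAAAACCgQAAAAAAAKKBAAAAAAAAwoEAAAAAAADigQAAAAAAAQKBAAAAAAABIoEAAAAAAAFCgQAAAAAAAWKBAAAAAAABgoEAAAAAAAGigQAAAAAAAcKBAAAAAAAB4oEAAAAAAAICgQAAAAAAAiKBAAAAAAACQoEAAAAAAAJigQAAAAAAAoKBAAAAAAACooEAAAAAAALCgQAAAAAAAuKBAAAAAAADAoEAAAAAAAMigQAAAAAAA0KBAAAAAAADYoEAAAAAAAOCgQAAAAAAA6KBAAAAAAADwoEAAAAAAAPigQAAAAAAAAKFAAAAAAAAIoUAAAAAAABChQAAAAAAAGKFAAAAAAAAgoUAAAAAAACihQAAAAAAAMKFAAAAAAAA4oUAAAAAAAEChQAAAAAAASKFAAAAAAABQoUAAAAAAAFihQAAAAAAAYKFAAAAAAABooUAAAAAAAHChQAAAAAAAeKFAAAAAAACAoUAAAAAAAIihQAAAAAAAkKFAAAAAAACYoUAAAAAAAKChQAAAAAAAqKFAAAAAAACwoUAAAAAAALihQAAAAAAAwKFAAAAAAADIoUAAAAAAANChQAAAAAAA2KFAAAAAAADgoUAAAAAAAOihQAAAAAAA8KFAAAAAAAD4oUAAAAAAAACiQAAAAAAACKJAAAAAAAAQokAAAAAAABiiQAAAAAAAIKJAAAAAAAAookAAAAAAADCiQAAAAAAAOKJAAAAAAABAokAAAAAAAEiiQAAAAAAAUKJAAAAAAABYokAAAAAAAGCiQAAAAAAAaKJAAAAAAABwokAAAAAAAHiiQAAAAAAAgKJAAAAAAACIokAAAAAAAJCiQAAAAAAAmKJAAAAAAACgokAAAAAAAKiiQAAAAAAAsKJAAAAAAAC4okA=</binary>
          </binaryDataArray>
          <binaryDataArray encodedLength="1068">
            <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>
            <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>
            <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>
            <binary>AAAAAABAj0AAAAAAAECPQAAAAAAAQI9AAAAAAABAj0AAAAAAAECPQAAAAAAAQI9AAAAAAABAj0AAAAAAAECPQAAAAAAAQI9AAAAAAABAj0AAAAAAAECPQAAAAAAAQI9AAAAAAABAj0AAAAAAAECPQAAAAAAAQI9AAAAAAABAj0AAAAAAAECPQAAAAAAAQI9AAAAAAABAj0AAAAAAAECPQAAAAAAAQI9AAAAAAABAj0AAAAAAAECPQAAAAAAAQI9AFgAAAABAj0DCFQAAAECPQHoYDgAAQI9A9fbaBQBAj0D4qT6PAUCPQFK+fi5EQI9A6e/bPXdHj0CaTINfL8aPQLG8cxwvpZJAnw7x0Yz4okBuFxygw1a+QEQsYlTnDNVA6RY82JsJ5EAAAAAAAOfoQOkWPNibCeRARCxiVOcM1UBuFxygw1a+QJ8O8dGM+KJAsbxzHC+lkkCaTINfL8aPQOnv2z13R49AUr5+LkRAj0D4qT6PAUCPQPX22gUAQI9AehgOAABAj0DCFQAAAECPQBYAAAAAQI9AAAAAAABAj0AAAAAAAECPQAAAAAAAQI9AAAAAAABAj0AAAAAAAECPQAAAAAAAQI9AAAAAAABAj0AAAAAAAECPQAAAAAAAQI9AAAAAAABAj0AAAAAAAECPQAAAAAAAQI9AAAAAAABAj0AAAAAAAECPQAAAAAAAQI9AAAAAAABAj0AAAAAAAECPQAAAAAAAQI9AAAAAAABAj0AAAAAAAECPQAAAAAAAQI9AAAAAAABAj0AAAAAAAECPQAAAAAAAQI9AAAAAAABAj0AAAAAAAECPQAAAAAAAQI9AAAAAAABAj0AAAAAAAECPQAAAAAAAQI9AAAAAAABAj0AAAAAAAECPQAAAAAAAQI9AAAAAAABAj0AAAAAAAECPQAAAAAAAQI9AAAAAAABAj0AAAAAAAECPQAAAAAAAQI9AAAAAAABAj0AAAAAAAECPQAAAAAAAQI9AAAAAAABAj0AAAAAAAECPQAAAAAAAQI9AAAAAAABAj0AAAAAAAECPQAAAAAAAQI9AAAAAAABAj0A=</binary>
          </binaryDataArray>
        </binaryDataArrayList>
      </spectrum>
    </spectrumList>
  </run>
</mzML>
</indexedmzML>
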